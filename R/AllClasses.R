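## S4 classes for the package's central objects. All constructors canonicalize
## ordering (C-collation sort on identifiers) so that value-identical objects
## are identical() — the sync module's exact replay guarantees rely on this.

#' Attributed network
#'
#' An attributed, optionally directed network of nodes and interaction-typed
#' edges; the universal currency of the package. Node identity is the `id`
#' column of `@nodes`; edge identity is the triple (from, interaction, to),
#' with (a, i, b) and (b, i, a) identified in undirected mode. Extra columns
#' of the node/edge data frames are the element attributes.
#'
#' @slot nodes data.frame with character column `id` plus attribute columns.
#' @slot edges data.frame with character columns `from`, `to`, `interaction`
#'   plus attribute columns.
#' @slot directed single logical.
#' @exportClass NetGraph
setClass("NetGraph", representation(
  nodes = "data.frame",
  edges = "data.frame",
  directed = "logical"
))

setValidity("NetGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  if (!"id" %in% names(n)) return("@nodes must have an 'id' column")
  if (!all(c("from", "to", "interaction") %in% names(e))) {
    return("@edges must have 'from', 'to' and 'interaction' columns")
  }
  if (nrow(n) && (!is.character(n$id) || any(is.na(n$id)) || any(!nzchar(n$id)))) {
    return("node ids must be non-empty strings")
  }
  if (anyDuplicated(n$id)) return("node ids must be unique")
  if (nrow(e)) {
    bad <- setdiff(c(e$from, e$to), n$id)
    if (length(bad)) {
      return(sprintf("dangling edge endpoint(s): %s",
                     paste(head(idSort(bad), 5), collapse = ", ")))
    }
    if (anyDuplicated(edgeKey(e$from, e$interaction, e$to))) {
      return("duplicate (from, interaction, to) edges")
    }
  }
  if (length(object@directed) != 1L || is.na(object@directed)) {
    return("@directed must be a single TRUE/FALSE")
  }
  TRUE
})

#' Single-attribute table
#'
#' One named attribute over element ids, as read from a Cytoscape node/edge
#' attribute file. The value kind is homogeneous: `"number"` iff every value
#' parses as a number, otherwise `"text"`.
#'
#' @slot name attribute name (first line of the file).
#' @slot entries named vector (numeric or character), names are element ids.
#' @slot valueKind `"text"` or `"number"`.
#' @exportClass AttributeTable
setClass("AttributeTable", representation(
  name = "character",
  entries = "ANY",
  valueKind = "character"
))

setValidity("AttributeTable", function(object) {
  if (length(object@name) != 1L) return("@name must be a single string")
  if (!object@valueKind %in% c("text", "number")) {
    return("@valueKind must be 'text' or 'number'")
  }
  if (length(object@entries)) {
    ids <- names(object@entries)
    if (is.null(ids) || any(!nzchar(ids))) return("entry ids must be non-empty")
    if (object@valueKind == "number" && !is.numeric(object@entries)) {
      return("numeric kind requires numeric entries")
    }
  }
  TRUE
})

#' Time-course value table
#'
#' Per-element numeric values over an ordered sequence of frames (time points
#' or experimental conditions).
#'
#' @slot frameLabels ordered, unique frame labels.
#' @slot values numeric matrix, one row per element id (rownames), one column
#'   per frame.
#' @exportClass TimeSeriesTable
setClass("TimeSeriesTable", representation(
  frameLabels = "character",
  values = "matrix"
))

setValidity("TimeSeriesTable", function(object) {
  if (anyDuplicated(object@frameLabels)) return("frame labels must be unique")
  if (ncol(object@values) != length(object@frameLabels)) {
    return("one value column per frame required")
  }
  if (nrow(object@values) && is.null(rownames(object@values))) {
    return("value rows must be named by element id")
  }
  TRUE
})

#' Velvet assembly graph
#'
#' Content of a Velvet LastGraph file: length/coverage-annotated nodes and
#' orientation-signed arcs. Node ids are positive integers; arc endpoints are
#' signed node ids (the sign encodes which strand/end of the node the arc
#' touches); `multiplicity` is the number of reads supporting the arc.
#'
#' @slot nodes data.frame: `id` (integer), `length` (k-mer count) plus any
#'   coverage columns (`cov1`, `cov2`, ...).
#' @slot arcs data.frame: `from`, `to` (signed integers), `multiplicity`.
#' @slot hashLength the k-mer length k.
#' @slot sequenceCount declared number of sequences (header field).
#' @slot sequences list keyed by node id: the two sequence lines per NODE
#'   block (stored verbatim, not validated as DNA).
#' @exportClass AssemblyGraph
setClass("AssemblyGraph", representation(
  nodes = "data.frame",
  arcs = "data.frame",
  hashLength = "numeric",
  sequenceCount = "numeric",
  sequences = "list"
))

setValidity("AssemblyGraph", function(object) {
  nd <- object@nodes
  ar <- object@arcs
  if (!all(c("id", "length") %in% names(nd))) {
    return("@nodes needs 'id' and 'length' columns")
  }
  if (nrow(nd) && (any(nd$id <= 0) || anyDuplicated(nd$id))) {
    return("assembly node ids must be unique positive integers")
  }
  if (!all(c("from", "to", "multiplicity") %in% names(ar))) {
    return("@arcs needs 'from', 'to' and 'multiplicity' columns")
  }
  if (nrow(ar)) {
    if (any(ar$multiplicity < 1)) return("arc multiplicity must be >= 1")
    bad <- setdiff(c(abs(ar$from), abs(ar$to)), nd$id)
    if (length(bad)) {
      return(sprintf("arc references undeclared node id(s): %s",
                     paste(head(bad, 5), collapse = ", ")))
    }
  }
  TRUE
})

#' 3D layout state
#'
#' Node coordinates produced by a layout run, together with the parameters
#' that produced them and force-evaluation accounting.
#'
#' @slot positions numeric matrix n x 3, rownames are node ids, columns
#'   x/y/z; all coordinates finite.
#' @slot params the resolved layout parameter list (see [layoutParams()]).
#' @slot forceEvaluations total count of pairwise repulsive force
#'   evaluations across all iterations and levels.
#' @slot evalLog data.frame with one row per (level, iteration): columns
#'   `level` (node count of the graph refined at that level), `iteration`,
#'   `repulsionEvals`, `attractionEvals`.
#' @exportClass LayoutState
setClass("LayoutState", representation(
  positions = "matrix",
  params = "list",
  forceEvaluations = "numeric",
  evalLog = "data.frame"
))

setValidity("LayoutState", function(object) {
  p <- object@positions
  if (ncol(p) != 3L) return("@positions must have 3 columns")
  if (nrow(p)) {
    if (is.null(rownames(p))) return("@positions rows must be named by node id")
    if (any(!is.finite(p))) return("all coordinates must be finite")
  }
  TRUE
})

#' One level of the multilevel coarsening hierarchy
#'
#' @slot coarseGraph the coarsened [NetGraph-class].
#' @slot parentMap named character vector mapping every fine node id to its
#'   coarse supernode id (total and onto the coarse node set).
#' @exportClass CoarseningLevel
setClass("CoarseningLevel", representation(
  coarseGraph = "NetGraph",
  parentMap = "character"
))

setValidity("CoarseningLevel", function(object) {
  cids <- object@coarseGraph@nodes$id
  if (is.null(names(object@parentMap))) return("@parentMap must be named")
  if (!all(object@parentMap %in% cids)) {
    return("parent map targets missing from coarse graph")
  }
  if (!setequal(unique(object@parentMap), cids)) {
    return("parent map must be onto the coarse node set")
  }
  TRUE
})

#' Visual style
#'
#' Ranges and colour scheme used when mapping numeric values onto node sizes,
#' edge thicknesses and colours.
#'
#' @slot sizeRange min/max node radius.
#' @slot thicknessRange min/max edge width.
#' @slot colorScheme named scheme (`"heatmap"`) or `"custom"`.
#' @slot ramp three colour anchors (low, mid, high) of the value ramp.
#' @slot defaultColor colour used where no value mapping applies.
#' @exportClass VisualStyle
setClass("VisualStyle", representation(
  sizeRange = "numeric",
  thicknessRange = "numeric",
  colorScheme = "character",
  ramp = "character",
  defaultColor = "character"
))

setValidity("VisualStyle", function(object) {
  for (rng in list(object@sizeRange, object@thicknessRange)) {
    if (length(rng) != 2L || any(!is.finite(rng)) || any(rng <= 0) ||
        rng[1] >= rng[2]) {
      return("ranges must be positive with min < max")
    }
  }
  if (length(object@ramp) != 3L) return("@ramp needs exactly 3 colour anchors")
  TRUE
})

#' Renderable 3D scene
#'
#' A graph plus its 3D layout and per-element visual state (node size/colour,
#' edge thickness/colour, highlight labels). Every styled or positioned
#' element exists in the graph. `@sequence` is the last mutation-event
#' sequence number applied (0 for a freshly built scene).
#'
#' @slot graph the [NetGraph-class].
#' @slot layout the [LayoutState-class]; positions cover exactly the nodes.
#' @slot nodeSize,nodeColor named by node id.
#' @slot edgeThickness,edgeColor named by edge key (see [edgeKeys()]).
#' @slot highlighted character vector of highlighted node ids.
#' @slot sequence last applied event sequence number.
#' @exportClass Scene
setClass("Scene", representation(
  graph = "NetGraph",
  layout = "LayoutState",
  nodeSize = "numeric",
  nodeColor = "character",
  edgeThickness = "numeric",
  edgeColor = "character",
  highlighted = "character",
  sequence = "numeric"
))

setValidity("Scene", function(object) {
  ids <- object@graph@nodes$id
  keys <- edgeKeys(object@graph)
  pos <- object@layout@positions
  if (!setequal(rownames(pos), ids) || nrow(pos) != length(ids)) {
    return("layout must position exactly the graph's nodes")
  }
  for (nm in c("nodeSize", "nodeColor")) {
    if (!all(names(slot(object, nm)) %in% ids)) {
      return(sprintf("@%s styles a node missing from the graph", nm))
    }
  }
  for (nm in c("edgeThickness", "edgeColor")) {
    if (!all(names(slot(object, nm)) %in% keys)) {
      return(sprintf("@%s styles an edge missing from the graph", nm))
    }
  }
  if (!all(object@highlighted %in% ids)) {
    return("highlight set contains unknown node id")
  }
  TRUE
})

#' Motion network
#'
#' An ordered sequence of condition/time frames over a union graph, stored as
#' per-frame topology mutation events: replaying events for frames 1..t from
#' the empty graph reproduces frame t exactly.
#'
#' @slot unionGraph union of all frame elements.
#' @slot frameLabels ordered unique frame labels.
#' @slot events list (one entry per frame) of ordered mutation events
#'   transforming frame t-1 into frame t; frame 1 events build it from empty.
#' @exportClass MotionNetwork
setClass("MotionNetwork", representation(
  unionGraph = "NetGraph",
  frameLabels = "character",
  events = "list"
))

setValidity("MotionNetwork", function(object) {
  if (length(object@events) != length(object@frameLabels)) {
    return("one event batch per frame required")
  }
  if (anyDuplicated(object@frameLabels)) return("frame labels must be unique")
  TRUE
})
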