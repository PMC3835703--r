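# Scene JSON (format `netscene3d-scene`, version 1)

A single UTF-8 JSON object describing one renderable 3D network scene.
Written by `exportScene()`, read by `importScene()`. Numbers are emitted at
17 significant digits, so export → import is exact on IEEE doubles.

```json
{
  "format": "netscene3d-scene",
  "version": 1,
  "directed": false,
  "sequence": 0,
  "nodes": [
    {
      "id": "contig510",
      "x": 1.25, "y": -0.5, "z": 0.75,
      "size": 25,
      "color": "#AAAAAA",
      "highlighted": false,
      "attributes": {"length": 42, "cov1": 1200}
    }
  ],
  "edges": [
    {
      "source": "contig510",
      "target": "contig511",
      "interaction": "arc",
      "thickness": 4.5,
      "color": "#AAAAAA",
      "attributes": {"multiplicity": 27}
    }
  ]
}
```

Field notes:

* `sequence` — the last mutation-event sequence number applied to this
  scene (0 for a freshly built scene); lets a mirror resume a stream.
* `directed` — edge semantics; in undirected scenes `source`/`target` are
  stored in canonical (C-collation) order.
* `size` / `thickness` — node radius and edge width in visual-style units.
* `color` — `#RRGGBB`.
* `highlighted` — whether the node carries a search-highlight label.
* `attributes` — the element's own attribute mapping (text or numbers);
  empty object/array when there are none.

An animation (`exportAnimation()`) is a JSON array of these objects, one
per frame, in frame order.
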