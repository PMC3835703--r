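# Scene synchronization stream

The wire format used by `writeSceneStream()` / `readSceneStream()` and the
CLI `serve` / `mirror` subcommands: newline-delimited JSON (NDJSON) over any
byte stream (file, pipe, socket connection). One record per line.

## Records

1. **snapshot** — always the first record; the full state of the scene at
   the subscriber's join point:

   ```json
   {"type": "snapshot", "scene": { ...scene JSON object... }}
   ```

   The embedded scene object is exactly the `netscene3d-scene` format (see
   `scene-format.md`), including its `sequence` counter.

2. **event** — one mutation event, in log order:

   ```json
   {"type": "event", "seq": 7, "kind": "insert", "target": "node",
    "id": "X", "payload": {"id": "X", "x": 0.1, "y": 2.0, "z": -1.0,
    "size": 25, "color": "#AAAAAA", "highlighted": false,
    "attributes": {}}}
   ```

   * `seq` — server-assigned, strictly increasing, contiguous from the
     snapshot's `sequence`.
   * `kind` — `insert` | `delete` | `update`.
   * `target` — `node` | `edge` (structure or attributes) | `style`
     (visual state and position).
   * `id` — node id, or edge key `"from|interaction|to"`.
   * `payload` — full element record for inserts; `{"attributes": ...}`
     for attribute updates; element-tagged visual record for style updates
     (`{"element": "node", "x": ..., "size": ..., ...}` or
     `{"element": "edge", "thickness": ..., "color": ...}`). Deletes carry
     no payload.

## Ordering and consistency rules

* Within one batch (one `sceneDiff`): edge deletes, node deletes, node
  inserts, edge inserts, attribute updates, style updates — each class
  sorted by element id. Deletes therefore always precede inserts for the
  same id.
* A consumer applies events only at `sequence + 1`; anything at or below
  its counter is *stale*, anything beyond is *out of order* — both are
  synchronization errors, and the consumer's recovery is to rejoin and
  receive a fresh snapshot.
* Replay is exact: two consumers of the same stream prefix hold
  byte-identical serialized scenes.
* Clients are read-only mirrors; there is exactly one writer per stream.
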