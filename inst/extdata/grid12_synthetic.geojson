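{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":"r1c1"},"geometry":{"type":"Polygon","coordinates":[[[0,2],[1,2],[1,3],[0,3],[0,2]]]}},{"type":"Feature","properties":{"id":"r1c2"},"geometry":{"type":"Polygon","coordinates":[[[1,2],[2,2],[2,3],[1,3],[1,2]]]}},{"type":"Feature","properties":{"id":"r1c3"},"geometry":{"type":"Polygon","coordinates":[[[2,2],[3,2],[3,3],[2,3],[2,2]]]}},{"type":"Feature","properties":{"id":"r1c4"},"geometry":{"type":"Polygon","coordinates":[[[3,2],[4,2],[4,3],[3,3],[3,2]]]}},{"type":"Feature","properties":{"id":"r2c1"},"geometry":{"type":"Polygon","coordinates":[[[0,1],[1,1],[1,2],[0,2],[0,1]]]}},{"type":"Feature","properties":{"id":"r2c2"},"geometry":{"type":"Polygon","coordinates":[[[1,1],[2,1],[2,2],[1,2],[1,1]]]}},{"type":"Feature","properties":{"id":"r2c3"},"geometry":{"type":"Polygon","coordinates":[[[2,1],[3,1],[3,2],[2,2],[2,1]]]}},{"type":"Feature","properties":{"id":"r2c4"},"geometry":{"type":"Polygon","coordinates":[[[3,1],[4,1],[4,2],[3,2],[3,1]]]}},{"type":"Feature","properties":{"id":"r3c1"},"geometry":{"type":"Polygon","coordinates":[[[0,0],[1,0],[1,1],[0,1],[0,0]]]}},{"type":"Feature","properties":{"id":"r3c2"},"geometry":{"type":"Polygon","coordinates":[[[1,0],[2,0],[2,1],[1,1],[1,0]]]}},{"type":"Feature","properties":{"id":"r3c3"},"geometry":{"type":"Polygon","coordinates":[[[2,0],[3,0],[3,1],[2,1],[2,0]]]}},{"type":"Feature","properties":{"id":"r3c4"},"geometry":{"type":"Polygon","coordinates":[[[3,0],[4,0],[4,1],[3,1],[3,0]]]}}]}
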