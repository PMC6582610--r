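{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "DDP instance",
  "description": "A double digest problem instance: fragment-length multisets from digesting one molecule with enzyme A alone (a), enzyme B alone (b), and both together (c). Lengths are non-negative integers; a solvable instance has equal totals.",
  "type": "object",
  "required": ["a", "b", "c"],
  "properties": {
    "name": { "type": "string" },
    "a": { "type": "array", "items": { "type": "integer", "minimum": 0 }, "minItems": 1 },
    "b": { "type": "array", "items": { "type": "integer", "minimum": 0 }, "minItems": 1 },
    "c": { "type": "array", "items": { "type": "integer", "minimum": 0 }, "minItems": 1 }
  }
}
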