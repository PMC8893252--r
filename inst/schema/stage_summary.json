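{
  "description": "Shape of the per-stage JSON summaries written by run_pipeline(): a flat object with a string 'stage' field and scalar (number, string or boolean) metric fields.",
  "type": "object",
  "required": ["stage"],
  "properties": {
    "stage": {"type": "string"}
  },
  "additionalProperties": {"type": ["number", "string", "boolean"]}
}
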