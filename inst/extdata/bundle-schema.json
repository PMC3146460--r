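{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "phosdelta report bundle",
  "type": "object",
  "required": ["version", "config", "globalDeltaDelta", "localDeltaDelta",
               "entropy", "rotamers", "distributions"],
  "properties": {
    "version": {"type": "string"},
    "config": {"type": "object"},
    "globalDeltaDelta": {"type": "array"},
    "localDeltaDelta": {"type": "array"},
    "shell": {"type": "object"},
    "entropy": {"type": "array"},
    "entropyPerDihedral": {"type": "array"},
    "entropyUnmatched": {"type": "array"},
    "rotamers": {"type": "object"},
    "distributions": {"type": "array"}
  }
}
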