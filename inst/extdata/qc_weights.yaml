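# Default quality-check weight configuration (must sum to 100).
# Half the budget sits on the minimal requirements; the remaining check
# types share the rest evenly.
minimal_req: 50
mandatory_req: 10
length: 10
datatype: 10
permissible: 10
range: 10
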