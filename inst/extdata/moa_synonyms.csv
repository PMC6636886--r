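synonym,moa_id
self-efficacy,4
self efficacy,4
perceived self-efficacy,4
attitude toward the behavior,17
attitude towards the behaviour,17
memory attention and decision processes,10
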