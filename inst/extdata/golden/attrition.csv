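stage,reason,count
stage1,older than maximum entry age at patient start,1
stage1,patient window outside practice window,2
stage1,practice window empty,2
stage2,exclusion (ever recorded): Palliative,1
stage2,exposure order violated,2
stage2,outcome before index: Stroke,1
stage2,prevalent at entry: Diabetes,2
stage4,potential control not selected,11
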