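# disease_count: 1000
phecode,pair_count
290.11,0
296.2,120
345,85
365,4
288.6,10
377.3,60
299,500
433,25
800,2
807,0
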