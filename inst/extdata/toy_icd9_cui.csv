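icd9,cui
331.0,C0002395
296.21,C0154409
296.31,C0154415
311,C0011581
345.10,C0014544
345.90,C0014544
365.9,C0017601
365.11,C0017612
288.60,C0023508
288.8,C0023508
377.30,C0029132
377.39,C0029132
299.00,C0004352
299.80,C0004352
800.00,C0036416
803.00,C0036416
807.00,C0035522
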