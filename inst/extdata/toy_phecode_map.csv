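icd9,phecode,phecode_label,exclude_range
296.21,296.2,Depression,296-296.99
296.31,296.2,Depression,296-296.99
311,296.2,Depression,296-296.99
331.0,290.11,Alzheimer's disease,290-294.99
345.10,345,Epilepsy,345-345.99
345.90,345,Epilepsy,345-345.99
365.9,365,Glaucoma,
365.11,365,Glaucoma,
288.60,288.6,Elevated white blood cell count,
288.8,288.6,Elevated white blood cell count,
377.30,377.3,Optic neuritis,377-377.99
377.39,377.3,Optic neuritis,377-377.99
299.00,299,Autism spectrum disorder,299-299.99;313-313.99
299.80,299,Autism spectrum disorder,299-299.99;313-313.99
433.10,433,Occlusion of cerebral arteries,
800.00,800,Fracture of skull,
803.00,800,Fracture of skull,
807.00,807,Fracture of ribs,
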