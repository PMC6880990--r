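cui,string
C0002395,alzheimer's disease
C0002395,alzheimers disease
C0002395,senile dementia
C0154409,major depressive disorder single episode mild
C0154415,major depressive disorder recurrent episode mild
C0011581,depressive disorder
C0011581,depression
C0014544,epilepsy
C0014544,seizure disorder
C0017601,glaucoma
C0017612,primary open angle glaucoma
C0023508,leukocytosis
C0023508,elevated white blood cell count
C0029132,optic neuritis
C0004352,autism
C0004352,autistic disorder
C0036416,skull fracture
C0036416,fracture of skull
C0035522,rib fracture
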