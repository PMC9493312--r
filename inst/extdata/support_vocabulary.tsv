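experiment	strength
qRT-PCR	strong
RT-PCR	strong
Western blot	strong
Northern blot	strong
Luciferase reporter assay	strong
Reporter assay	strong
GFP reporter assay	strong
5'RACE	strong
Immunohistochemistry	strong
Flow cytometry	strong
ELISA	strong
Immunoblot	strong
CLIP-Seq	weak
CLIP-seq	weak
HITS-CLIP	weak
PAR-CLIP	weak
iCLIP	weak
CLASH	weak
CLEAR-CLIP	weak
pSILAC	weak
SILAC	weak
Microarray	weak
RNA-seq	weak
NGS	weak
Next Generation Sequencing (NGS)	weak
Degradome sequencing	weak
Proteomics	weak
Sequencing	weak
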