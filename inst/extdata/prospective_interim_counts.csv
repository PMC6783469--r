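who_classification,tumour_type,who_grade,label,count
Diffuse astrocytic and oligodendroglial tumours,Glioblastoma multiforme,IV,cancer,4
Diffuse astrocytic and oligodendroglial tumours,Anaplastic astrocytoma,III,cancer,3
Diffuse astrocytic and oligodendroglial tumours,Oligoastrocytoma,II,cancer,2
Embryonal tumours,Medulloblastoma,IV,cancer,1
Ependymal tumours,Ependymoma,II,cancer,1
Diffuse astrocytic and oligodendroglial tumours,Gliosarcoma,IV,cancer,1
Control,,,non-cancer,92
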