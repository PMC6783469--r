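who_classification,tumour_type,who_grade,label,count
Diffuse astrocytic and oligodendroglial tumours,Glioblastoma multiforme,IV,cancer,260
Diffuse astrocytic and oligodendroglial tumours,Gliosarcoma,IV,cancer,4
Diffuse astrocytic and oligodendroglial tumours,Oligodendroglioma,II,cancer,11
Diffuse astrocytic and oligodendroglial tumours,Diffuse astrocytoma,II,cancer,23
Diffuse astrocytic and oligodendroglial tumours,Anaplastic astrocytoma,III,cancer,10
Diffuse astrocytic and oligodendroglial tumours,Oligoastrocytoma,II,cancer,3
Diffuse astrocytic and oligodendroglial tumours,Glioma,I,cancer,7
Other astrocytic tumours,Pilocytic astrocytoma,I,cancer,9
Other astrocytic tumours,Pleomorphic xanthoastrocytoma,II,cancer,1
Tumours of the cranial and paraspinal nerves,Schwannoma,I,cancer,14
Ependymal tumours,Ependymoma,II,cancer,6
"Mesenchymal, non-meningothelial tumours",Haemangiopericytoma,II/III,cancer,2
"Mesenchymal, non-meningothelial tumours",Haemanglioblastoma,I,cancer,1
Neuronal and mixed neuronal-glial tumours,Ganglioglioma,I,cancer,1
Embryonal tumours,Medulloblastoma,IV,cancer,1
Tumours of the pineal region,PPTID,II/III,cancer,1
Meningiomas,Meningioma,I,cancer,46
Pituitary tumours,Pituitary adenoma,,cancer,29
Lymphomas,Lymphoma,,cancer,2
Metastatic tumours,Metastasis,,cancer,56
Control,,,non-cancer,237
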