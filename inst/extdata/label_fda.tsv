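term	canonical
diarrhoea	
nausea	
vomiting	
weight decreased	
insomnia	
headache	
decreased appetite	
dizziness	
tremor	
back pain	
anxiety	
suicidal ideation	
depression	
abdominal pain upper	
muscle spasms	
atrial fibrillation	
rash	
influenza	
nasopharyngitis	
neoplasm malignant	
lung neoplasm malignant	
urinary tract infection	
weight loss	weight decreased
decreased weight	weight decreased
diarrhea	diarrhoea
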