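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
malaise	
nervousness	
sleep disorder	
weight loss	weight decreased
diarrhea	diarrhoea
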