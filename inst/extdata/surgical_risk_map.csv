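procedure,level
cataract extraction,low
carpal tunnel release,low
cystoscopy,low
skin lesion excision,low
breast biopsy,low
endoscopic procedure,low
laparoscopic cholecystectomy,moderate
total knee arthroplasty,moderate
total hip arthroplasty,moderate
hysterectomy,moderate
carotid endarterectomy,moderate
head and neck surgery,moderate
open aortic repair,high
peripheral vascular bypass,high
major emergency laparotomy,high
pneumonectomy,high
esophagectomy,high
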