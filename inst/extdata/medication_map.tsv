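# Editable medication lexicon: free-text label -> rule class.
label	class
insulin	insulin
insulin_glargine	insulin
metformin	metformin
glibenclamide	sulfonylurea
gliclazide	sulfonylurea
glimepiride	sulfonylurea
semaglutide	glp1_or_weightloss
liraglutide	glp1_or_weightloss
glp1	glp1_or_weightloss
orlistat	glp1_or_weightloss
weightloss_rx	glp1_or_weightloss
ace_inhibitor	antihypertensive
beta_blocker	antihypertensive
amlodipine	antihypertensive
antihypertensive	antihypertensive
statin	lipid_lowering
atorvastatin	lipid_lowering
simvastatin	lipid_lowering
fibrate	lipid_lowering
aspirin	antiplatelet_anticoagulant
clopidogrel	antiplatelet_anticoagulant
warfarin	antiplatelet_anticoagulant
apixaban	antiplatelet_anticoagulant
levothyroxine	other
vitamin_d	other
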