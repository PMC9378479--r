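drug_name,atc_code
hydrochlorothiazide,C03AA03
furosemide,C03CA01
bumetanide,C03CA02
spironolactone,C03DA01
triamterene,C03DB02
enalapril,C09AA02
lisinopril,C09AA03
perindopril/indapamide,C09BA04
losartan,C09CA01
valsartan,C09CA03
metoprolol,C07AB02
bisoprolol,C07AB07
amlodipine,C08CA01
diltiazem,C08DB01
doxazosin,C02CA04
isosorbide mononitrate,C01DA14
digoxin,C01AA05
flecainide,C01BC04
amiodarone,C01BD01
temazepam,N05CD07
oxazepam,N05BA04
zopiclone,N05CF01
haloperidol,N05AD01
quetiapine,N05AH04
citalopram,N06AB04
sertraline,N06AB06
amitriptyline,N06AA09
nortriptyline,N06AA10
mirtazapine,N06AX11
venlafaxine,N06AX16
duloxetine,N06AX21
acenocoumarol,B01AA07
phenprocoumon,B01AA04
rivaroxaban,B01AF01
apixaban,B01AF02
dalteparin,B01AB04
enoxaparin,B01AB05
fondaparinux,B01AX05
acetylsalicylic acid,B01AC06
clopidogrel,B01AC04
ibuprofen,M01AE01
naproxen,M01AE02
diclofenac,M01AB05
morphine,N02AA01
oxycodone,N02AA05
fentanyl,N02AB03
tramadol,N02AX02
metformin,A10BA02
gliclazide,A10BB09
sitagliptin,A10BH01
insulin glargine,A10AE04
prednisolone,H02AB06
dexamethasone,H02AB02
amoxicillin,J01CA04
ciprofloxacin,J01MA02
nitrofurantoin,J01XE01
levodopa/carbidopa,N04BA02
pramipexole,N04BC05
oxybutynin,G04BD04
tolterodine,G04BD07
promethazine,R06AD02
valproic acid,N03AG01
levetiracetam,N03AX14
simvastatin,C10AA01
atorvastatin,C10AA05
omeprazole,A02BC01
pantoprazole,A02BC02
paracetamol,N02BE01
levothyroxine,H03AA01
metoclopramide,A03FA01
allopurinol,M04AA01
colecalciferol,A11CC05
calcium carbonate,A12AA04
macrogol,A06AD15
lactulose,A06AD11
alendronic acid,M05BA04
ferrous fumarate,B03AA02
folic acid,B03BB01
salbutamol,R03AC02
tiotropium,R03BB04
tamsulosin,G04CA02
latanoprost,S01EE01
hydrocortisone cream,D07AA02
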