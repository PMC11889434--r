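synonym,ingredient
semaglutide,semaglutide
ozempic,semaglutide
wegovy,semaglutide
rybelsus,semaglutide
dulaglutide,dulaglutide
trulicity,dulaglutide
liraglutide,liraglutide
victoza,liraglutide
saxenda,liraglutide
tirzepatide,tirzepatide
mounjaro,tirzepatide
monjaro,tirzepatide
zepbound,tirzepatide
empagliflozin,empagliflozin
jardiance,empagliflozin
dapagliflozin,dapagliflozin
farxiga,dapagliflozin
forxiga,dapagliflozin
canagliflozin,canagliflozin
invokana,canagliflozin
metformin,metformin
glucophage,metformin
fortamet,metformin
glumetza,metformin
sitagliptin,sitagliptin
januvia,sitagliptin
linagliptin,linagliptin
tradjenta,linagliptin
trajenta,linagliptin
alogliptin,alogliptin
nesina,alogliptin
vildagliptin,vildagliptin
galvus,vildagliptin
saxagliptin,saxagliptin
onglyza,saxagliptin
pioglitazone,pioglitazone
actos,pioglitazone
orlistat,orlistat
xenical,orlistat
alli,orlistat
bupropion,bupropion
wellbutrin,bupropion
zyban,bupropion
topiramate,topiramate
topamax,topiramate
qsymia,topiramate
phentermine,phentermine
adipex,phentermine
adipex p,phentermine
lomaira,phentermine
naltrexone,naltrexone
revia,naltrexone
vivitrol,naltrexone
contrave,naltrexone
insulin glargine,insulin glargine
lantus,insulin glargine
toujeo,insulin glargine
basaglar,insulin glargine
semglee,insulin glargine
rosuvastatin,rosuvastatin
crestor,rosuvastatin
glyburide,glyburide
glibenclamide,glyburide
diabeta,glyburide
micronase,glyburide
glynase,glyburide
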