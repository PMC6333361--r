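group,long_name,type,domain,B,PB,QB,PQ,EE,GS,BA,NM
SB,Seabirds,consumer,pelagic,0.11990005745306202,0.3369539797554899,1.7811242704296584,,,0.2,0,0
MM,Marine mammals,consumer,pelagic,0.01817614046676642,0.2005810269554786,0.9897475229771676,,,0.2,0,0
TUR,Sea turtles,consumer,pelagic,0.02867130860143986,0.3556596363073914,1.4614008901255375,,,0.2,0,0
XIP,Sword fish,consumer,pelagic,0.057246394319524156,0.41390739862967174,1.6728967266879284,,,0.2,0,-0.005096112339040565
THU,Bluefin tuna,consumer,pelagic,0.12184264308847144,0.39210795509003227,1.4008141875794957,,,0.2,0,0
LPL,Large pelagic fish,consumer,pelagic,0.05268722253597519,0.3157295082349447,1.5886300051823854,,,0.2,0,0
MPL,Medium pelagic fish,consumer,pelagic,0.3809334054466771,0.33421830917912304,1.895686917126882,,,0.2,0,0
SPL,Other small pelagic fish,consumer,pelagic,0.27244742857268445,1.3789771642594133,5.413920107580003,,,0.2,0,0
HAK0,European hake <6 cm,consumer,demersal,0.04107547865277238,1.991706709493883,10.862464216705387,,,0.2,0,0
HAK1,European hake 6-12 cm,consumer,demersal,0.032831835832883446,0.40331455795472726,1.5113529687001062,,,0.2,0,0
HAK2,European hake 12.1-22 cm,consumer,demersal,0.06948201067573798,0.45711316292145066,4.568403189464729,,,0.2,0,0
HAK3,European hake 22.1-41 cm,consumer,demersal,0.081865568281165,0.3369613171713718,1.0217110781096415,,,0.2,0,0
HAK4,European hake >41 cm,consumer,demersal,5.681589480109223e-4,0.3373669177392731,0.99038389235522994,,,0.2,0,0
MUL0,Red mullet <8 cm,consumer,demersal,0.1446496816146006,1.8367130979895592,9.838459493658895,,,0.2,0,0
MUL1,Red mullet 8-12 cm,consumer,demersal,0.9946965419046861,1.9524118474975696,9.780576173659682,,,0.2,0,0
MUL2,Red mullet 12.1-17 cm,consumer,demersal,0.14130705993190096,0.6435237323786716,4.229743680485562,,,0.2,0,0
MUL3,Red mullet >17 cm,consumer,demersal,0.30393211571101025,0.44366458009346393,1.3312924882936241,,,0.2,0,0
TRA,Horse mackerel,consumer,demersal,0.11164879336174614,0.8135934499520228,2.4549365908302927,,,0.2,0,0
PAG,Pandora,consumer,demersal,0.062081388874968,0.3093383085777168,1.0910496889134016,,,0.2,0,0
DFS,Demersal fish (slope),consumer,demersal,0.06751653143785155,0.5698785124212737,3.1095364455922523,,,0.2,0,0
DFH,Demersal fish crustacean feeders (shelf),consumer,demersal,0.05586952676402974,0.6683364632644226,2.92148725219561,,,0.2,0,0
DSM,Demersal fish mixed food (shelf),consumer,demersal,0.10837049079805097,0.3048631303015282,1.0659786256000605,,,0.2,0,0
DSP,Demersal fish piscivorous (shelf),consumer,demersal,0.004361261889684431,0.20035297813912623,1.2650073442583736,,,0.2,0,0
DSR,Demersal fish rocky (shelf),consumer,demersal,0.20671100752874827,0.7159618367784425,2.8100096968100172,,,0.2,0,0
MSC,Mesopelagic fish crustacean feeders (slope),consumer,demersal,0.17261778953032905,0.4156653162973817,1.6201401293194486,,,0.2,0,0
MSG,Mesopelagic fish jelly feeders (slope),consumer,demersal,0.03115302353765204,0.5582113117771224,3.6179492753458047,,,0.2,0,0
MSP,Mesopelagic fish piscivorous (slope),consumer,demersal,0.034845513341106304,0.2909171094477643,1.0348340786128876,,,0.2,0,0
RSH,Rays and skates (shelf),consumer,demersal,0.11600999528839027,0.7613415938187974,4.939227755170433,,,0.2,0,0
RSS,Rays and skates (slope),consumer,demersal,0.1363826297068095,0.8536148082691946,4.327879774986224,,,0.2,0,0
SSH,Sharks (shelf),consumer,demersal,0.03268874793542947,0.35647652116997053,1.0937928209058505,,,0.2,0,0
SSS,Sharks (slope),consumer,demersal,0.10331497171546096,0.41189833212250965,1.6418892660239388,,,0.2,0,0
ENG,European anchovy,consumer,pelagic,0.46668873244344483,1.2862705454346723,4.342967465753315,,,0.2,0,0
SAR,European pilchard,consumer,pelagic,1.4786912005730966,1.7541423238115388,15.985386125617568,,,0.2,0,0
EPI,Epipelagic fish,consumer,pelagic,0.7142490653853262,0.6812186336028389,2.3719407017237346,,,0.2,0,0
CEBH,Cephalopods benthic (shelf),consumer,demersal,0.15656498191433613,0.7032346989566578,2.095368072572721,,,0.2,0,0
CEBS,Cephalopods benthic (slope),consumer,demersal,0.09420401311665702,0.4693872837658274,1.3779084785151794,,,0.2,0,0
CEPH,Cephalopods pelagic (shelf),consumer,demersal,0.3219219621510074,0.36752369096298937,1.2897205379131995,,,0.2,0,0
CEPS,Cephalopods pelagic (slope),consumer,demersal,0.05513339269559879,0.3644275510162698,1.2863141147965818,,,0.2,0,0
DNS,Decapods natant (slope),consumer,demersal,0.4808212737074961,1.9868428263987883,7.377278599968927,,,0.2,0,0
DNH,Decapods natant (shelf),consumer,demersal,0.3924456565700651,0.6865512813383247,4.807240675213229,,,0.2,0,0
DRS,Decapods reptant (slope),consumer,demersal,0.7174150639640859,1.002062882197788,6.063113758130582,,,0.2,0,0
DRH,Decapods reptant (shelf),consumer,demersal,0.4708560362465968,2.1028972172818614,9.198895324314085,,,0.2,0,0
ARF,Giant red shrimp,consumer,demersal,0.21757026778048838,1.6385513634304516,6.093493051774937,,,0.2,0,0
PWL,Deep water rose shrimp,consumer,demersal,0.6347054539932188,1.2728058038454038,3.6817760316046453,,,0.2,0,0
SUP,Suprabenthos,consumer,benthic,0.18563579713011777,1.3613402463379316,4.696121689987703,,,0.2,0,0
O,Macrobenthos omnivore,consumer,benthic,0.26239752089910945,0.7339538767584599,3.0376106261372624,,,0.2,0,0
FF,Macrobenthos filter-feeder,consumer,benthic,3.5542450420595526,4.078059101244435,31.52199959593255,,,0.2,0,0
DF,Macrobenthos deposit-feeder,consumer,benthic,6.914798841818088,1.9713330903323367,9.011838470662944,,,0.2,0,0
C,Macrobenthos carnivore,consumer,benthic,0.5504624966992039,2.2083253641903866,7.068395718961791,,,0.2,0,0
PAR,Macrobenthos parasite,consumer,benthic,0.25946288611990675,1.3550082170055249,9.194694697259656,,,0.2,0,0
SCA,Macrobenthos scavenger,consumer,benthic,0.07983295024099318,2.1831831397139467,13.0089478436793,,,0.2,0,0
H,Macrobenthos herbivore,consumer,benthic,3.889728378823079,3.7994730164064094,15.825652228408837,,,0.2,0,0
GRA,Macrobenthos grazer,consumer,benthic,9.97246965792169,3.9677267441293225,12.170647985252286,,,0.2,0,0
SF,Macrobenthos suspension-feeder,consumer,benthic,14.338803041004642,3.1020962168695405,23.033507832027198,,,0.2,0,0
PF,Macrobenthos particulate-feeder,consumer,benthic,0.9357450292297037,4.016892880783416,11.568627840859714,,,0.2,0,0
BO,Meiobenthos,consumer,benthic,,4.771352865034714,14.17231876323531,,0.2860850758178792,0.2,0,0
EUP,Euphausiacea,consumer,pelagic,,2.073213976167608,6.752268542171663,,0.09441754835461262,0.2,0,0
ZG,Gelatinous zooplankton,consumer,pelagic,0.527461734167499,1.6829665619123264,6.15791855478127,,,0.2,0,0
ZL,Large zooplankton,consumer,pelagic,1.0523579216664238,2.2042724113154692,13.764986424131433,,,0.2,0,0
ZM,Mesozooplankton,consumer,pelagic,3.61697236518407,2.394000885193236,19.84920821358485,,,0.2,0,0
ZS,Microzooplankton,consumer,pelagic,3.1603564411874476,3.118024878902361,13.642461986508295,,,0.2,0,0
PB,Pelagic bacteria,consumer,pelagic,6.575340262532955,4.790050829644315,24.247176981876486,,,0.2,0,0
BB,Sediment bacteria,consumer,benthic,8.624273365622503,4.923792499350384,15.083552766947724,,,0.2,0,0
PS,Pico-phytoplankton,producer,pelagic,42.70587076433003,183.81314826430753,,,,0,0,0
DFL,Dinoflagellates,producer,pelagic,53.68060953915119,188.04432852659374,,,,0,0,0
PL,Diatom,producer,pelagic,48.74574129469693,64.36651160940528,,,,0,0,0
MB,Microphytobenthos,producer,benthic,,167.78504895279184,,,0.007602876081964292,0,0,0
SG,Seagrass,producer,benthic,43.605596367269754,131.93164858967066,,,,0,0,0
MA,Macroalgae,producer,benthic,22.664926582947373,108.62823033472523,,,,0,0,0
DC,Detritus carrion,detritus,benthic,,,,,,0,0,0
SPOM,Suspended particulate organic matter,detritus,demersal,,,,,,0,0,0
BD,Benthic detritus,detritus,benthic,,,,,,0,0,0
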