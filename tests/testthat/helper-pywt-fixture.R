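# Frozen cross-library MODWT oracle: expected coefficients computed with
# PyWavelets 1.9 swt(norm=TRUE, trim_approx=TRUE) and mapped to the
# Percival-Walden phase convention used here:
#   W_j = -circshift(cD_j, (2^j - 1) L/2),  V_J = +circshift(cA_J, (2^J - 1) L/2).
pywt_fixture_x <- c(
  1.1044609999999999, 0.63167700000000004, -1.2705040000000001,
  -1.0654920000000001, 1.7759039999999999, 0.62839500000000004, -1.25132,
  0.166021, 0.16875299999999999, 1.8944399999999999, -0.15659400000000001,
  0.27620099999999997, -0.039042, -0.68740199999999996, 0.106269,
  -0.88697700000000002, -0.89754999999999996, -0.48197400000000001,
  0.73216300000000001, -1.209714, -0.416078, 1.0966800000000001,
  1.1212089999999999, 0.53424799999999995, 0.218002, -0.027576,
  -1.2568349999999999, 0.73208200000000001, 0.093869999999999995, -1.435883,
  0.077174999999999994, -0.531331)
pywt_fixture_la8_w1 <- c(
  0.13804909079181166, -0.88650011611023372, 0.59745896738477733,
  -0.60654461913927393, 0.72317586860505823, 0.35813246397857107,
  -0.9190379618215766, -0.53805756599990728, 1.4054428979920106,
  -0.016919098465482806, -1.0600632335254669, 0.45307442691095617,
  -0.28906586129897077, 0.94436148677861953, -0.80937303737888167,
  0.21860308384005828, 0.09436680417062468, -0.37024422235509552,
  0.58005770264850676, -0.32735849388715915, -0.20717516625060153,
  0.018126712270926992, 0.87628994211563704, -0.95027031334119916,
  -0.15188588094456254, 0.56194213036334828, 0.038537212626119144,
  -0.17466422641702606, 0.073819291244420451, 0.13796113487415831,
  -0.85235263635900838, 0.94011321669863646)
pywt_fixture_la8_w2 <- c(
  0.66714557041439815, 0.65623099813237629, 0.07704690176743613,
  -0.2175875696791128, -0.50649167115344851, -0.23545646108013479,
  0.48267995043787831, 0.16284460387358371, -0.58186847171808886,
  -0.33759893914550682, 0.42936342094009305, 0.8145292303406213,
  0.026982270825030512, -1.0862247828512315, -0.28119074251714238,
  1.0840744246734551, 0.28645334973728959, -0.99710534184049149,
  -0.49578384915334223, 0.60887668729098043, 0.67586288850337461,
  0.035970894102561601, -0.264087561600784, -0.16814136367302931,
  0.002439863033795165, 0.097617675295192191, -0.1887427187828209,
  -0.26883568648075074, 0.29545869169246153, 0.19896091307734204,
  -0.62526789242623282, -0.34815528203595775)
pywt_fixture_la8_w3 <- c(
  0.22899617899778438, 0.31133840885390107, 0.43374711926718623,
  0.31930685415151999, 0.08000111222741299, -0.14869470217096351,
  -0.40264718133642913, -0.46729842676603611, -0.42504623416365345,
  -0.38129426196881061, -0.25499312819904962, -0.081099835273173632,
  0.13080001087839252, 0.40420275215257656, 0.60715270377483088,
  0.59026282890061044, 0.37179296019368163, 0.089309195125179389,
  -0.22658671386848495, -0.43580402433411652, -0.3746393143457028,
  -0.31189484270588236, -0.17863440988107041, 0.06673365964255476,
  0.079132095410985329, 0.083826797306547629, 0.10665365700033452,
  -0.055349909140771779, -0.091036809198951893, -0.046793346592599525,
  -0.0846920467573688, 0.063248852819361434)
pywt_fixture_la8_v3 <- c(
  -0.069934792660185846, -0.22046327579952602, -0.32337902373701483,
  -0.34041423964818918, -0.32874472489333717, -0.27538967191907421,
  -0.18369629879590971, -0.082607670896459054, 0.0099612900021537887,
  0.13834140449972984, 0.23010784639739706, 0.22030670035835603,
  0.1798535046838913, 0.10547694716861539, 0.010504820528341573,
  -0.058876987694443939, -0.11331103423897837, -0.2045813244185693,
  -0.24453722538034006, -0.20266910977374594, -0.16065203907882497,
  -0.089712987401198888, -0.010098764502625542, 0.056586258780373745,
  0.14119428689641247, 0.25461294571899767, 0.30571815272020963,
  0.29068639906316218, 0.27745300928808075, 0.22753546215245499,
  0.15119999277053964, 0.052808149809707459)
pywt_fixture_c6_w1 <- c(
  0.51071293810953866, -0.56280966876028227, 0.70498202321775938,
  0.46678353410773765, -0.83728092734041826, -0.77348101813792558,
  1.3471314052821999, 0.22671066233347803, -1.0768576718967553,
  0.29021314623547662, -0.31671959995821158, 1.0969756888919733,
  -0.68078383808544973, 0.15824476046283512, 0.089098610440189963,
  -0.3994942029166843, 0.51428669129354976, -0.28948271350178617,
  -0.23528624305847992, -0.11222967076191612, 0.91933314734144889,
  -0.87067564283964127, -0.28430778860457245, 0.549329716369235,
  0.24662776096442021, -0.094726950520370654, 0.011738506410835165,
  0.17162869024673733, -0.93523169328175992, 0.83862862311202446,
  0.26080067916570537, -0.93385895432089117)
pywt_fixture_c6_w2 <- c(
  -0.4584915626289835, -0.42057201685986079, 0.42445670515141987,
  0.1786353838385519, -0.58047001786506025, -0.38304177978898074,
  0.1860557628468881, 0.80579680814743304, 0.34589560415769965,
  -1.0586379553061451, -0.52678195247566395, 1.0397869868233653,
  0.43708946547144223, -0.8460534748917844, -0.54679349310800929,
  0.45687327136302308, 0.723371711299445, 0.15790626224523208,
  -0.13022431122392172, -0.126958091863697, -0.11113420013691762,
  0.063689940884248897, -0.23442715692547841, -0.45587039445476008,
  0.21694440611589041, 0.31929265007982693, -0.59034376892074281,
  -0.45126200839468106, 0.61176205753615365, 0.70910078074203753,
  0.23309075070583848, 0.011313637436190739)
pywt_fixture_c6_w3 <- c(
  -0.38213225462514133, -0.41058217377589246, -0.35740142797192004,
  -0.23187612955703271, -0.10955008536641284, 0.20503664066645236,
  0.53481105627866254, 0.60825058172740931, 0.45416212864554212,
  0.25134823628429925, -0.045093489256777107, -0.36404225601961349,
  -0.24261690906340816, -0.3276024361419928, -0.31782950529235993,
  0.04681726207473455, -0.0029305608230378892, 0.044316624133264711,
  0.15248971203217829, -0.064571988072174527, -0.099166299366984512,
  0.028375680575641361, -0.11676074094250329, -0.0080203016792591755,
  0.16131028229671088, 0.20387283940250217, 0.48524163216573563,
  0.38763711025558673, 0.22092369830273173, 0.0052345888557253162,
  -0.33545723701301605, -0.37419427872965055)
pywt_fixture_c6_v3 <- c(
  0.086700698890542272, -0.12434918332612445, -0.28088952420085295,
  -0.30027921626698306, -0.36084517689792783, -0.35767216472873026,
  -0.28470917057400941, -0.13120122119323152, -0.12352955362959006,
  0.044291978166056505, 0.25591904076940941, 0.26228545354926641,
  0.2308322101723512, 0.13410651719889499, 0.027483632940413394,
  -0.03867924308345367, -0.0092342369041818612, -0.1695860259380563,
  -0.27082412961991481, -0.17956955708455002, -0.15546756129728836,
  -0.069116272935984477, -0.05386588385034078, -0.044865389739358739,
  0.013972841643229535, 0.2175529810981239, 0.26370436305135808,
  0.1854730698022666, 0.25339027802286485, 0.26059167046581944,
  0.27900117148393655, 0.1826556040160438)
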