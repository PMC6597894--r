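preset_id,delta,n_members,drive_gain,cohesion_gain,drag,repulsion_scale,n_passes,center_freq_hz,bandwidth_hz,peak_gain,fs
p01,               0.5,                20,0.0043448278565065834,                 1,0.041668577505617588,                 0,                 2,4.7107935324220644,  2.37762823860501,2.7548788225704044,              1000
p02,               0.5,                20,0.0097984027744475455,                 1,0.062561936725765488,                 0,                 2,7.0895443536987379,3.5841175334293345,2.7436319073162174,              1000
p03,               0.5,                20,0.022039889103995236,                 1,0.093803952655263867,                 0,                 2, 10.66793994518426,5.4227262088241339,2.7270911926034649,              1000
p04,               0.5,                20,0.049374275996466821,                 1,0.14035747857756276,                 0,                 2, 16.04922373416381, 8.233943437716869,2.7031400563613808,              1000
p05,               0.5,                20,0.10989870938078639,                 1,0.20935485603792303,                 0,                 2,24.139404701294296,12.494092550293594,2.6688155529285904,              1000
p06,               0.5,                20,0.24206683276726171,                 1,0.31076533888375302,                 0,                 2,36.297821326650578,19.189015801681048,2.6215327757915357,              1000
p07,               0.5,                20,0.5239075207200008,                 1,0.45785650042855552,                 0,                 2, 54.57333486654526,29.497136302424543,2.5597721250872425,              1000
p08,               0.5,                20,1.0997129321667387,                 1,0.66665745821301736,                 0,                 2,82.109490998003977,46.387404558835819,2.4858598888187413,              1000
p09,               0.5,                20,2.1823374016073731,                 1,0.95236010961746009,                 0,                 2,124.01818511965628,73.538900865602997,2.4163027046310259,              1000
p10,               0.5,                20,3.8806877296563522,                 1,1.3175769366426011,                 0,                 2,190.59729329080116,122.57022212960636,2.4119513273326132,              1000
p11,               0.5,                20,6.2102105064172131,                 1,               1.5,                 0,                 2,311.73407244025265, 171.9972385268988,4.7166988197511461,              1000
p12,               0.5,                20,14.087606917325108,0.19619654133744646,0.37999999999999989,                 0,                 2,453.01430119630857,23.726364135490087,3590.1096928812649,              1000
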