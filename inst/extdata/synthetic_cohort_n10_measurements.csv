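subject_id,observer,observation,method,A_mm,B_mm
1,1,1,software-3d,9.462123383882965,6.461788398130186
1,1,2,software-3d,9.12329542668007,6.619066773692431
1,2,1,software-3d,9.664788731920352,6.641117591222086
1,2,2,software-3d,10.137516974110886,6.018936011938567
2,1,1,software-3d,9.012805401438415,6.724720265390189
2,1,2,software-3d,9.440288558418864,6.902972140514561
2,2,1,software-3d,9.211105936830249,6.680563897366808
2,2,2,software-3d,9.695941959017128,7.06470132626565
3,1,1,software-3d,10.824626345850781,6.7836388295259535
3,1,2,software-3d,9.81544034097938,6.926076930533722
3,2,1,software-3d,9.778718292182726,6.498058371744261
3,2,2,software-3d,10.196640567180824,7.505812501527984
4,1,1,software-3d,8.563147143787537,6.562281130657212
4,1,2,software-3d,8.2169221907619,6.051720954946548
4,2,1,software-3d,8.602976521648495,6.2244088953227
4,2,2,software-3d,8.542030878462624,6.69800420259926
5,1,1,software-3d,9.78341360938977,7.664990319466024
5,1,2,software-3d,10.379915046316144,7.5915363635050825
5,2,1,software-3d,9.052010032914659,7.547806435987559
5,2,2,software-3d,9.81230462099115,6.636993819888287
6,1,1,software-3d,9.164058410602278,6.177730562374102
6,1,2,software-3d,8.776132954649471,6.739947287822082
6,2,1,software-3d,9.489555013642978,6.582816991969417
6,2,2,software-3d,8.940984066974206,6.651722133720369
7,1,1,software-3d,9.084342848113787,7.048724074816124
7,1,2,software-3d,9.02523190596569,6.85002861593436
7,2,1,software-3d,9.122259158145066,7.4271221386316455
7,2,2,software-3d,9.43645798136793,7.061771709250728
8,1,1,software-3d,8.957139474299927,7.023583700223435
8,1,2,software-3d,8.837617373405337,6.908067239321046
8,2,1,software-3d,9.82374998822118,6.916647533112169
8,2,2,software-3d,9.899478761345387,6.7913875353220705
9,1,1,software-3d,8.78108418903049,7.411624795588394
9,1,2,software-3d,9.1452559134886,7.074929709892541
9,2,1,software-3d,9.128883780441948,6.999432174034333
9,2,2,software-3d,9.057385799705111,7.784838442849167
10,1,1,software-3d,8.730967745816272,6.116029095827108
10,1,2,software-3d,9.18625605156401,6.5206792895957255
10,2,1,software-3d,9.23478177193277,6.716364927017536
10,2,2,software-3d,8.979851287664586,6.508845442650126
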