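subject_id,observer,actual_angular_c1_deg,actual_angular_tip_deg
1,1,548.2361024109133,588.9651086807812
1,2,553.0868184762479,593.8158247461158
2,1,498.54466304838274,534.8676734136407
2,2,513.3021409862504,549.6251513515083
3,1,469.39951762836336,504.2333621364515
3,2,488.20082980994937,523.0346743180374
4,1,621.3939006622983,669.1146857211085
4,2,623.292786831421,671.0135718902312
5,1,463.9225052702299,495.7604797766482
5,2,472.46619730453364,504.3041718109519
6,1,561.9422323423537,606.7304857406365
6,2,567.5689985506896,612.3572519489724
7,1,503.59612848947313,540.2852783498064
7,2,519.5000420760468,556.18919193638
8,1,551.5052573070653,590.9029282978361
8,2,538.4661837543313,577.863854745102
9,1,509.91225707116763,546.0520637450736
9,2,516.3903743103269,552.5301809842329
10,1,602.5732139837801,648.7834544825706
10,2,598.3223107696726,644.5325512684632
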