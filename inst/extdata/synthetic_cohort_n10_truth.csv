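subject_id,A_true_mm,B_true_mm,shortfall_mm,actual_linear_c1_mm,true_angular_c1_deg,true_angular_tip_deg
1,9.35752889510044,6.625339991003579,0.23543811586815883,26.56456188413184,552.6493934420639,593.3783997119318
2,9.347443008171755,7.106873968620949,0.31966429107948796,26.480335708920514,507.99546519728074,544.3184755625387
3,10.046137236953367,6.885635159694393,1.0981749972676762,25.701825002732324,482.1589054521077,516.9927499601959
4,8.35582007709921,6.355183175663205,0.37746185884850714,26.422538141151495,616.7576645161299,664.4784495749401
5,9.659857712185437,7.664648821149645,0.06506811335864493,26.734931886641355,465.1229765194724,496.96095102589067
6,8.993310413913525,6.154290423396193,1.477215054764137,25.322784945235863,571.0241954758733,615.8124488741561
7,9.21545677682756,7.057585789324943,0.6019961754679698,26.19800382453203,507.64349230268346,544.3326421630167
8,9.42135750236454,6.734276124564381,0.26878890179934833,26.531211098200654,539.1860722527875,578.5837432435583
9,9.257697586793345,7.211153590536137,0.0633490178047057,26.736650982195297,509.757126700447,545.8969333743529
10,8.919222443214311,6.26130196257065,0.39378606265970706,26.406213937340294,602.3090833479346,648.5193238467251
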