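# Nominal sRGB values of the classic 24-patch colour reference chart
# (widely published post-2014 nominal values). The CIELab columns are
# derived from these sRGB nominals under D65 / IEC 61966-2-1 decoding,
# i.e. a synthetic reference consistent with the package colour pipeline;
# any published chart edition may be substituted (the calibration
# regression is invariant to affine re-specification of the reference).
chip_id,name,R,G,B,L,a_star,b_star
1,dark_skin,115,82,68,38.017,11.797,13.664
2,light_skin,194,150,130,65.667,13.675,16.899
3,blue_sky,98,122,157,50.628,0.371,-21.6
4,foliage,87,108,67,42.998,-15.876,20.451
5,blue_flower,133,128,177,55.684,12.763,-25.169
6,bluish_green,103,189,170,70.994,-30.638,1.537
7,orange,214,126,44,61.136,28.104,56.131
8,purplish_blue,80,91,166,41.121,17.409,-41.881
9,moderate_red,193,90,99,51.329,42.096,14.883
10,purple,94,60,108,31.101,24.355,-22.099
11,yellow_green,157,188,64,71.896,-28.104,56.957
12,orange_yellow,224,163,46,71.038,12.603,64.915
13,blue,56,61,150,30.351,26.434,-49.669
14,green,70,148,73,55.033,-40.137,32.297
15,red,175,54,60,41.345,49.303,24.66
16,yellow,231,199,31,80.704,-3.664,77.548
17,magenta,187,86,149,51.144,48.147,-15.283
18,cyan,8,133,161,51.15,-19.73,-23.373
19,white,243,243,242,95.817,-0.176,0.481
20,neutral_8,200,200,200,80.604,0,0
21,neutral_6_5,160,160,160,65.868,0,0
22,neutral_5,122,122,121,51.195,-0.2,0.546
23,neutral_3_5,85,85,85,36.146,0,0
24,black,52,52,52,21.704,0,0
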