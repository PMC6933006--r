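"dialect","corruption","mean_lc","sd_lc","n_strokes"
"inertial",0,8.28475059001803,0.254154989264974,125
"inertial",0.5,8.2986680114037,0.248045029413466,125
"inertial",1,8.16131771147372,0.280235781757468,125
"inertial",2,7.72074788292053,0.424043102511292,125
"inertial",3,7.09876102626222,0.564481660410645,125
"inertial",4,6.55322168126388,0.683683608864989,125
"inertial",6,5.44342317566276,0.686846386268824,125
"inertial",8,5.26595512455816,0.997441171446696,125
"optical",0,7.52643759301008,0.276022196196839,125
"optical",0.5,7.54393784758484,0.300850368947321,125
"optical",1,7.49798245467161,0.257203839198919,125
"optical",2,7.21830228256508,0.398656361299242,125
"optical",3,6.7451850319867,0.471445655088441,125
"optical",4,6.27080803450354,0.638772915406862,125
"optical",6,5.46418678873447,0.750795509050755,125
"optical",8,5.38441873006546,0.878156495768663,125
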