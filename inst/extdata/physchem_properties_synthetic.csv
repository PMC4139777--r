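property,A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y
hydropathy_kd,1.8,2.5,-3.5,-3.5,2.8,-0.4,-3.2,4.5,-3.9,3.8,1.9,-3.5,-1.6,-3.5,-4.5,-0.8,-0.7,4.2,-0.9,-1.3
residue_mass,71.08,103.14,115.09,129.12,147.18,57.05,137.14,113.16,128.17,113.16,131.19,114.1,97.12,128.13,156.19,87.08,101.1,99.13,186.21,163.18
volume_zamyatnin,88.6,108.5,111.1,138.4,189.9,60.1,153.2,166.7,168.6,166.7,162.9,114.1,112.7,143.8,173.4,89,116.1,140,227.8,193.6
polarity_grantham,8.1,5.5,13,12.3,5.2,9,10.4,5.2,11.3,4.9,5.7,11.6,8,10.5,10.5,9.2,8.6,5.9,5.4,6.2
isoelectric_point,6,5.07,2.77,3.22,5.48,5.97,7.59,6.02,9.74,5.98,5.74,5.41,6.3,5.65,10.76,5.68,5.6,5.96,5.89,5.66
helix_propensity_cf,1.42,0.7,1.01,1.51,1.13,0.57,1,1.08,1.16,1.21,1.45,0.67,0.57,1.11,0.98,0.77,0.83,1.06,1.08,0.69
sheet_propensity_cf,0.83,1.19,0.54,0.37,1.38,0.75,0.87,1.6,0.74,1.3,1.05,0.89,0.55,1.1,0.93,0.75,1.19,1.7,1.37,1.47
synthetic_08,-0.806,-0.073,-1.381,0.641,-2.725,-1.22,-1.38,-2.4,0.183,1.95,-1.458,-0.363,-2.242,0.996,2.915,-2.899,0.927,-1.764,-0.158,-0.244
synthetic_09,-1.25,2.065,-0.113,1.774,-2.226,2.299,2.262,-1.98,2.673,-2.085,1.046,1.268,-2.405,0.313,-2.574,0.255,2.382,0.448,0.629,-1.743
synthetic_10,0.358,1.902,-1.717,-1.338,2.078,1.591,2.895,-0.855,2.896,-0.583,2.973,-0.385,-0.546,1.575,1.395,0.156,2.14,2.53,2.287,2.026
synthetic_11,-0.706,0.687,-2.977,-2.21,0.839,1.949,-1.148,-1.667,-1.45,-0.405,-2.842,-2.711,-0.249,2.563,-0.596,-2.364,-1.915,-2.751,-0.033,-0.333
synthetic_12,-2.899,0.789,0.349,-1.777,-2.976,1.317,1.115,-1.639,0.8,2.268,1.837,2.014,2.681,-0.681,-0.024,2.63,-1.003,2.714,-1.487,1.326
synthetic_13,-0.824,-1.214,-1.723,-2.07,-0.261,-0.099,-0.331,1.325,1.188,-1.441,-2.167,-0.261,-0.032,0.031,1.619,-2.244,-2.959,1.302,-1.219,-2.048
synthetic_14,-1.246,2.649,-2.837,0.912,1.379,-1.745,-2.383,0.768,-2.838,1.566,-2.39,0.626,2.597,2.009,-2.332,-2.979,2.094,-2.799,0.379,2.121
synthetic_15,2.264,-2.189,0.319,-0.328,0.341,-1.325,-2.192,-0.657,-0.281,2.334,-0.279,1.523,-1.588,2.682,1.89,-0.721,2.824,2.454,-0.469,0.581
synthetic_16,0.439,0.572,-0.525,1.831,2.763,2.972,0.711,-1.652,-1.364,-2.589,1.342,0.532,0.758,2.303,-0.125,-0.781,1.193,-0.943,-1.583,2.542
synthetic_17,-2.189,-0.753,2.306,0.071,-0.186,-0.029,-0.837,-2.232,-2.523,0.357,-2.237,1.024,-0.883,-0.471,0.392,-0.01,2.233,-0.804,-0.915,1.797
synthetic_18,-0.957,-0.865,1.087,0.261,-0.155,2.401,1.888,-2.824,0.569,1.806,0.892,2.008,0.238,1.401,-2.259,-0.731,-0.534,2.221,-1.893,-1.859
synthetic_19,1.302,1.138,-1.62,0.731,-2.562,1.845,0.96,-2.773,1.267,1.131,-1.406,1.269,1.307,0.514,-0.339,-0.991,2.317,-1.23,2.134,2.339
synthetic_20,1.461,0.173,-0.5,-1.05,2.437,-1.679,-1.421,-0.08,2.933,-0.987,-2.307,-0.811,2.877,-0.163,-2.182,-0.046,-0.65,-1.024,-1.114,-0.981
synthetic_21,-1.877,-2.485,0.777,-1.029,0.207,-1.168,-0.813,-1.372,-0.04,1.559,0.654,-1.878,2.722,1.089,2.135,2.676,2.626,-0.706,0.573,1.103
synthetic_22,-0.546,0.878,0.327,-0.158,2.653,-2.885,1.134,2.648,-0.212,-1.906,-2.258,-2.719,-2.585,-1.116,2.106,-1.885,2.605,2.393,-1.809,-0.778
synthetic_23,2.911,1.412,-2.288,0.86,-2.318,2.515,2.12,-1.692,1.839,2.817,-0.101,1.151,2.266,-1.488,0.561,0.161,-2.902,-2.756,0.282,-1.662
synthetic_24,-0.514,-0.424,-0.618,1.445,-0.372,2.275,2.124,1.145,-1.385,-0.376,-2.599,2.514,0.352,-2.212,-0.513,-2.712,-2.544,2.278,2.311,-1.957
synthetic_25,-0.122,1.055,-2.15,2.8,0.607,1.132,-2.359,-0.485,-1.483,-2.957,-2.745,0.076,-1.169,-2.36,-1.522,2.316,-0.381,-1.505,0.258,-1.477
synthetic_26,1.801,-0.25,-2.829,1.906,-0.325,-0.038,1.324,0.615,-1.343,0.058,0.589,-1.376,1.575,-1.449,1.233,2.88,0.312,-2.752,-0.984,1.624
synthetic_27,2.425,1.531,2.631,-0.681,-0.763,-2.906,-1.326,-1.325,0.157,0.198,0.352,-1.306,-2.074,2.108,1.02,2.751,-1.99,-0.446,-0.651,-0.604
synthetic_28,2.275,-2.659,-2.087,0.624,-2.7,-1.438,-2.666,1.956,-2.214,-0.355,2.006,2.815,0.507,2.162,-0.369,2.931,1.051,-1.778,-2.784,1.442
synthetic_29,0.795,2.043,0.654,1.341,2.233,1.684,-0.007,2.723,1.941,-2.884,0.145,-0.536,-1.314,2.266,0.688,-1.152,-2.45,-1.079,0.153,-2.031
synthetic_30,-0.663,-2.976,2.148,-1.268,2.203,0.892,-1.021,2.875,-2.817,-2.194,-1.667,1.101,-1.294,1.614,0.027,-0.469,0.707,0.426,2.698,1.773
synthetic_31,2.859,0.874,-0.012,-0.305,-0.347,2.674,-2.963,1.869,2.564,0.4,2.549,1.988,-2.249,1.392,0.707,0.897,-2.366,-1.167,-2.61,2.395
synthetic_32,-1.474,2.027,1.231,-2.002,0.477,-0.554,-0.502,-2.631,2.375,1.523,-0.575,-0.377,1.896,0.896,2.91,-1.476,-0.603,-2.77,0.782,0.858
synthetic_33,0.29,-1.537,-0.241,2.662,0.197,-2.158,-2.462,0,-1.437,2.113,-0.338,-2.52,2.836,1.061,0.096,-2.449,0.561,2.286,1.731,-1.692
synthetic_34,-2.734,0.823,-0.048,-0.188,1.546,1.783,1.566,0.339,0.64,-0.873,-2.449,-2.047,-1.798,1.579,2.047,-0.206,-1.872,-1.851,-0.447,2.599
synthetic_35,-1.754,0.774,-0.662,1.082,1.78,1.814,-1.313,-1.718,-0.841,-2.138,-0.969,1.865,-0.836,1.876,2.476,-1.596,-2.583,2.035,1.219,-0.317
synthetic_36,-0.539,-2.126,2.535,2.058,-2.726,-1.828,-1.423,-2.956,-1.898,-0.411,1.551,0.542,2.456,-1.791,0.369,2.878,0.677,1.004,2.686,2.094
synthetic_37,-2.452,-0.301,-2.076,-1.593,1.7,-1.786,-2.137,2.966,0.694,-2.882,1.526,-0.85,2.967,-1.391,0.753,-0.986,1.018,2.076,0.89,-0.153
synthetic_38,-2.944,2.367,1.964,2.568,-2.327,0.107,0.354,2.411,2.033,1.1,-2.868,0.434,2.868,2.189,1.834,-2.263,-0.135,-1.6,1.516,-0.056
synthetic_39,0.215,-0.802,-0.01,-0.829,-0.46,-0.043,2.45,0.866,0.454,-0.614,-1.488,0.384,-2.267,0.52,-0.636,0.004,0.866,2.36,-0.316,-0.578
synthetic_40,-0.161,-0.925,-2.475,-1.683,1.19,-2.283,2.672,-1.742,1.789,1.056,0.833,-2.18,0.199,1.917,-1.61,-1.062,2.163,-0.2,1.597,-0.626
synthetic_41,-2.056,-0.345,-2.082,1.287,2.745,1.54,-2.28,-2.851,1.221,2.834,0.197,2.589,0.474,-1.528,2.51,2.057,1.854,-1.192,-1.515,-0.507
synthetic_42,1.169,-0.67,-1.051,1.771,-1.896,0.992,1.322,-2.489,-1.462,2.956,-0.272,-0.684,1.887,2.575,2.88,-2.965,-0.939,2.81,-2.991,0.549
synthetic_43,-1.939,2.569,-1.451,-0.172,2.605,-1.081,-2.615,-0.529,-1.088,2.792,-0.992,2.507,-1.394,2.699,-0.018,1.307,-2.978,2.582,2.471,-0.651
synthetic_44,1.592,-0.796,0.781,2.062,-1.307,-1.401,-0.915,2.743,-0.877,0.979,-2.777,-1.682,-1.555,1.448,0.819,0.153,0.75,-1.274,2.583,-1.11
synthetic_45,-1.011,-1.279,-2.148,1.517,1.264,1.188,2.542,-0.47,0.264,1.552,0.051,2.456,2.966,-2.458,-2.593,-0.931,2.99,-2.929,2.882,1.1
synthetic_46,-2.477,2.921,-0.829,0.355,-1.16,0.126,-1.428,-1.181,-0.169,2.201,1.957,-0.58,2.594,-0.07,0.067,-0.507,-1.688,-2.085,-2.256,-2.844
synthetic_47,-0.028,2.522,-1.485,-0.314,-1.382,0.211,2.462,1.09,-2.092,2.02,-2.177,-2.342,-2.649,-0.3,-2.381,-2.969,2.579,1.062,1.799,2.759
synthetic_48,2.713,2.52,2.748,2.526,2.772,2.573,-0.647,0.809,0.137,-1.811,-2.698,-1.6,-2.687,-2.261,0.637,1.935,1.249,1.108,2.114,-0.983
synthetic_49,-2.268,1.145,2.799,0.164,-0.949,2.592,1,1.147,2.467,2.427,-0.059,-1.424,1.702,1.545,1.506,-2.156,-1.754,-0.483,-0.406,-1.727
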