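aa,hydrophilicity,flexibility,accessibility,turn_propensity,exposed_surface,polarizability,antigenic_propensity,hydrophobicity_kd,hydrophobicity_cons,net_charge_index,polarity_grantham,polarity_zimmerman,sasa,side_chain_volume
A,-0.5,0.357,0.3,0.66,15,0.046,0.115,1.8,0.62,0.007187,8.1,0.00,118.1,27.5
R,3.0,0.529,-1.4,0.95,67,0.291,0.058,-4.5,-2.53,0.043587,10.5,52.00,256.0,105.0
N,0.2,0.463,-0.5,1.56,49,0.134,-0.077,-3.5,-0.78,0.005392,11.6,3.38,165.5,58.7
D,3.0,0.511,-0.6,1.46,50,0.105,0.065,-3.5,-0.90,-0.023820,13.0,49.70,158.7,40.0
C,-1.0,0.346,0.9,1.19,5,0.128,-0.120,2.5,0.29,-0.036610,5.5,1.48,146.1,44.6
Q,0.2,0.493,-0.7,0.98,56,0.180,-0.011,-3.5,-0.85,0.049211,10.5,3.53,193.2,80.7
E,3.0,0.497,-0.7,0.74,55,0.151,-0.071,-3.5,-0.74,0.006802,12.3,49.90,186.2,62.0
G,0.0,0.544,0.3,1.56,10,0.000,-0.184,-0.4,0.48,0.179052,9.0,0.00,88.1,0.0
H,-0.5,0.323,-0.1,0.95,34,0.230,0.312,-3.2,-0.40,-0.010690,10.4,51.60,202.5,79.0
I,-1.8,0.462,0.7,0.47,13,0.186,-0.292,4.5,1.38,0.021631,5.2,0.13,181.0,93.5
L,-1.8,0.365,0.5,0.59,16,0.186,0.036,3.8,1.06,0.051672,4.9,0.13,193.1,93.5
K,3.0,0.466,-1.8,1.01,85,0.219,0.206,-3.9,-1.50,0.017708,11.3,49.50,225.8,100.0
M,-1.3,0.295,0.4,0.60,20,0.221,-0.385,1.9,0.64,0.002683,5.7,1.43,203.4,94.1
F,-2.5,0.314,0.5,0.60,10,0.290,-0.141,2.8,1.19,0.037552,5.2,0.35,222.8,115.5
P,0.0,0.509,-0.3,1.52,45,0.131,-0.016,-1.6,0.12,0.239531,8.0,1.58,146.8,41.9
S,0.3,0.507,-0.1,1.43,32,0.062,-0.026,-0.8,-0.18,0.004627,9.2,1.67,129.8,29.3
T,-0.4,0.444,-0.2,0.96,32,0.108,-0.045,-0.7,-0.05,0.003352,8.6,1.66,152.5,51.3
W,-3.4,0.305,0.3,0.96,17,0.409,-0.114,-0.9,0.81,0.037977,5.4,2.10,266.3,145.5
Y,-2.3,0.420,-0.4,1.14,41,0.298,0.013,-1.3,0.26,0.023599,6.2,1.61,236.8,117.3
V,-1.5,0.386,0.6,0.50,14,0.140,-0.013,4.2,1.08,0.057004,5.9,0.13,164.5,71.5
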