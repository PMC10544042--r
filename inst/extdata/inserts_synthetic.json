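{"description":"Nominal tissue-surrogate phantom inserts (synthetic stand-ins for vendor compositions)","inserts":[{"name":"lung_inhale","rho":0.2,"elements":["H","C","N","O","Na","P","S","Cl","K"],"mass_fractions":[0.103,0.105,0.031,0.749,0.002,0.002,0.003,0.003,0.002]},{"name":"lung_exhale","rho":0.5,"elements":["H","C","N","O","Na","P","S","Cl","K"],"mass_fractions":[0.103,0.105,0.031,0.749,0.002,0.002,0.003,0.003,0.002]},{"name":"adipose","rho":0.96,"elements":["H","C","N","O","Na","S","Cl"],"mass_fractions":[0.114,0.598,0.007,0.278,0.001,0.001,0.001]},{"name":"breast","rho":0.99,"elements":["H","C","N","O","Na","P","S","Cl"],"mass_fractions":[0.11,0.465,0.0185,0.4025,0.001,0.0005,0.0015,0.001]},{"name":"muscle","rho":1.06,"elements":["H","C","N","O","Na","P","S","Cl","K"],"mass_fractions":[0.102,0.143,0.034,0.71,0.001,0.002,0.003,0.001,0.004]},{"name":"liver","rho":1.07,"elements":["H","C","N","O","Na","P","S","Cl","K"],"mass_fractions":[0.102,0.139,0.03,0.716,0.002,0.003,0.003,0.002,0.003]},{"name":"bone_200","rho":1.16,"elements":["Ca","P","O","H"],"mass_fractions":[0.0687829,0.031895,0.806369,0.0929529]},{"name":"bone_800","rho":1.53,"elements":["Ca","P","O","H"],"mass_fractions":[0.208597,0.0967273,0.640236,0.0544396]},{"name":"bone_1250","rho":1.82,"elements":["Ca","P","O","H"],"mass_fractions":[0.273998,0.127054,0.562524,0.036424]}]}
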