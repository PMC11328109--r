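# DSC thermodynamic parameters for the TmArgBP D2 domain (92 residues),
# pH 7.4, 20 mM sodium phosphate buffer.
# part: buffer = no cosolute; A = KSCN; B = GdmSCN; C = GdmCl;
#       D = 1 M GdmSCN + stabilizing agent.
part,cosolute,conc_M,td_C,dh_kJ_mol,dhvh_kJ_mol,ratio
buffer,none,0,102.6,470,490,0.96
A,KSCN,0.5,99.6,470,480,0.98
A,KSCN,1.0,97.0,436,450,0.97
A,KSCN,2.0,92.6,425,435,0.98
B,GdmSCN,0.5,90.2,405,409,0.99
B,GdmSCN,1.0,78.4,341,354,0.96
B,GdmSCN,1.5,64.5,256,265,0.97
B,GdmSCN,2.0,50.4,212,223,0.95
C,GdmCl,0.5,98.2,440,458,0.96
C,GdmCl,1.0,94.0,430,439,0.98
C,GdmCl,2.0,86.2,370,390,0.95
D,GdmSCN + 1 M TMAO,1.0,84.5,417,426,0.98
D,GdmSCN + 1 M sucrose,1.0,85.0,405,412,0.98
D,GdmSCN + 0.5 M TMAO + 0.5 M sucrose,1.0,84.6,417,424,0.98
D,GdmSCN + 0.5 M Na2SO4,1.0,91.1,420,415,1.01
D,GdmSCN + 1 M Na2SO4,1.0,99.6,417,427,0.97
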