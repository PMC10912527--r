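species,symmetry,shape_class,flower_size,hp_percent,n_stigmas,pattern,adj_r_squared,b,f_statistic,p_printed
Bid.pil,R,circle,488.5,0.5,54,increasing_linear,0.221,0.008,15.71,<.001
Can.mar,B,legume,861.3,11.3,50,increasing_linear,0.388,0.142,22.52,<.001
Cle.vis,B,flat_rect,204.0,0.9,54,increasing_linear,0.511,0.042,16.66,.001
Cor.sub,R,circle_plus_tube,2235.1,4.1,52,increasing_exponential,0.364,0.003,19.92,<.001
Eup.ato,R,circle,188.0,0,50,no_pattern,NA,NA,NA,NA
Eup.cya,R,circle,2333.9,3.9,51,no_pattern,-0.074,-0.012,0.24,.636
Gue.spe,R,circle_plus_tube,1069.4,0,51,no_pattern,NA,NA,NA,NA
Ipo.pes,R,circle_plus_tube,4454.6,25.4,50,increasing_exponential,0.175,0.012,10.53,.002
Ipo.vio,R,circle_plus_tube,9415.9,6.4,58,increasing_linear,0.08,0.048,5.94,.018
Mac.atr,B,legume,427.6,0.2,52,no_pattern,-0.021,0.00001,0.00,.962
Mes.arg,R,circle,22.9,38.1,50,no_pattern,-0.041,0.13,0.06,.803
Mor.cit,R,circle_plus_tube,260.7,33.3,50,no_pattern,0.022,0.01,1.89,.177
Pas.foe,R,circle,1073.7,2.3,54,no_pattern,-0.01,0.006,0.47,.494
Phy.nod,B,circle,4.2,1.9,51,no_pattern,-0.024,0.002,0.08,.778
Phy.min,R,circle_plus_tube,142.1,1.5,50,no_pattern,0.036,0.011,2.85,.098
Sca.tac,B,flat_rect,405.7,3.3,52,no_pattern,-0.015,0.002,0.26,.614
Ses.can,B,legume,147.6,1.1,52,no_pattern,0.005,0.004,1.26,.267
Ses.por,R,circle,148.0,1.9,52,no_pattern,0.002,-0.005,1.13,.293
Sid.aln,R,circle,136.7,1.6,50,no_pattern,-0.006,0.017,0.71,.404
Sol.pho,R,circle,47.4,10,50,increasing_linear,0.606,0.417,22.52,<.001
Sta.jam,B,rect_plus_tube,177.1,0.6,50,increasing_linear,0.145,0.034,7.96,.007
Sur.mar,R,circle,102.7,11.6,50,no_pattern,-0.039,-0.002,0.26,.617
Ter.cat,R,circle,45.5,0.6,50,no_pattern,-0.03,0.00007,0.01,.928
Tri.por,B,flat_rect,54.8,0.2,52,no_pattern,-0.011,0.001,0.43,.517
Tri.cis,R,circle,577.8,41.8,52,increasing_exponential,0.092,0.007,5.84,.02
Tri.pro,R,circle,158.5,0.5,54,no_pattern,-0.017,0.001,0.11,.746
Vig.mar,B,legume,396.7,10.3,50,no_pattern,-0.053,0.035,0.10,.754
Wed.bif,R,circle,590.5,1.2,53,no_pattern,-0.018,0.004,0.07,.788
Wed.tri,R,circle,843.5,4.2,51,increasing_exponential,0.367,0.004,18.42,<.001
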