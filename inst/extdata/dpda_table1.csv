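id,series,r1,r2,exp_log_inv_ic50,pred_log_inv_ic50,glide_xp,is_test
A07a,A,4-(CF3)-phenyl,4-(CF3)-phenyl,0.377,0.382,-7.75,FALSE
A07b,A,Phenyl,Phenyl,-1.568,-1.837,-9.10,FALSE
A07c,A,6-(CF3)-pyridin-3-yl,6-(CF3)-pyridin-3-yl,-2.114,-1.192,-10.84,FALSE
A07d,A,4-(OCF3)-phenyl,4-(OCF3)-phenyl,-0.820,-1.015,-6.83,FALSE
A07e,A,4-(tBu)-phenyl,4-(tBu)-phenyl,0.745,1.169,-6.83,FALSE
A07f,A,3-(CF3)-phenyl,3-(CF3)-phenyl,-0.204,-0.557,-7.71,FALSE
A11a,A,4-(CF3)-phenyl,Phenyl,0.854,-0.127,-10.85,FALSE
A11b,A,4-(CF3)-phenyl,4-(OMe)-phenyl,0.824,-0.132,-10.79,TRUE
A11c,A,4-(CF3)-phenyl,4-(F)-phenyl,1.143,0.285,-10.68,FALSE
A11d,A,4-(CF3)-phenyl,4-(OH)-phenyl,-0.914,-0.279,-9.33,FALSE
A11e,A,4-(CF3)-phenyl,3-(CN)-phenyl,-0.322,-0.164,-7.88,FALSE
A11f,A,4-(CF3)-phenyl,4-Morpholinophenyl,0.237,0.560,-7.97,FALSE
A11g,A,4-(CF3)-phenyl,Thiophen-2-yl,0.018,0.350,-10.28,FALSE
A11h,A,4-(CF3)-phenyl,Thiophen-3-yl,0.310,-0.012,-7.74,TRUE
A11i,A,4-(CF3)-phenyl,Furan-2-yl,-0.519,-0.470,-7.36,FALSE
A11j,A,4-(CF3)-phenyl,Furan-3-yl,-0.519,-1.487,-10.04,FALSE
A11k,A,4-(CF3)-phenyl,5-(Me)-furan-2-yl,0.469,-0.128,-10.59,FALSE
A11l,A,4-(CF3)-phenyl,Pyridin-3-yl,-1.531,-0.810,-10.70,TRUE
A11m,A,4-(CF3)-phenyl,Pyridin-4-yl,-1.204,-0.837,-10.81,FALSE
A11n,A,4-(CF3)-phenyl,Pyrimidin-5-yl,-2.380,-1.695,-10.48,FALSE
A11o,A,4-(CF3)-phenyl,Cyclohex-1-en-1-yl,0.481,0.452,-10.55,FALSE
A11p,A,4-(CF3)-phenyl,"3,6-Dihydro-2H-pyran-4-yl",-1.415,-0.467,-9.54,FALSE
A11s,A,4-(CF3)-phenyl,4-(NMe2)-phenyl,0.444,0.027,-11.05,TRUE
A20,A,4-(CF3)-phenyl,4-(CF3)-phenyl,-0.613,-0.127,-9.04,FALSE
A27a,A,4-(CF3)-phenyl,H,-2.973,-3.007,-8.52,TRUE
A27b,A,4-(CF3)-phenyl,Me,-2.978,-2.888,-10.09,FALSE
A27c,A,4-(CF3)-phenyl,nBu,-0.778,-0.711,-10.88,TRUE
A32,A,4-(CF3)-phenyl,4-(Morpholinomethyl)-phenyl,-0.204,0.663,-4.83,FALSE
B11aa,B,4-(CF3)-phenyl,2-(Piperidin-1-yl)-pyrimidin-5-yl,0.367,-0.600,-10.41,FALSE
B11ab,B,4-(CF3)-phenyl,4-(OH)-phenyl,-1.519,0.006,-11.32,FALSE
B11ac,B,4-(CF3)-phenyl,4-(OMe)-phenyl,0.602,0.024,-11.85,FALSE
B11ad,B,4-(CF3)-phenyl,4-(OCF3)-phenyl,0.854,-0.081,-10.94,FALSE
B11ae,B,4-(CF3)-phenyl,4-(OEt)-phenyl,0.409,0.335,-12.02,FALSE
B11af,B,4-(CF3)-phenyl,2-(OEt)-phenyl,-0.204,0.399,-11.85,FALSE
B11ag,B,4-(CF3)-phenyl,3-(OEt)-phenyl,0.046,0.062,-11.26,FALSE
B11ah,B,4-(CF3)-phenyl,6-(OEt)-pyridin-3-yl,-0.591,-0.607,-11.98,TRUE
B11ai,B,4-(Cl)-phenyl,4-(OEt)-phenyl,0.620,0.071,-9.34,FALSE
B11aj,B,4-(Me)-phenyl,4-(OEt)-phenyl,0.398,0.237,-8.96,FALSE
B11q,B,4-(CF3)-phenyl,4-(F)-phenyl,0.959,0.488,-10.90,FALSE
B11r,B,4-(CF3)-phenyl,Furan-2-yl,-0.806,-0.342,-11.42,FALSE
B11t,B,4-(CF3)-phenyl,4-(NMe2)-phenyl,-0.146,0.174,-10.17,FALSE
B11u,B,4-(CF3)-phenyl,Phenyl,0.420,0.222,-10.61,FALSE
B11v,B,4-(CF3)-phenyl,4-(Piperidin-1-yl)-phenyl,0.585,1.327,-12.59,TRUE
B11w,B,4-(CF3)-phenyl,6-(NMe2)-pyridin-3-yl,-0.813,-0.656,-10.22,FALSE
B11x,B,4-(CF3)-phenyl,6-(Pyrrolidin-1-yl)-pyridin-3-yl,-0.342,-0.006,-11.63,FALSE
B11y,B,4-(CF3)-phenyl,6-(Piperidin-1-yl)-pyridin-3-yl,0.187,0.447,-12.38,FALSE
B11z,B,4-(CF3)-phenyl,2-(NMe2)-pyrimidin-5-yl,-1.415,-1.671,-11.18,FALSE
B36a,B,4-(CF3)-phenyl,4-(O-nPr)-phenyl,1.097,0.573,-11.86,FALSE
B36b,B,4-(CF3)-phenyl,4-(O-iPr)-phenyl,0.854,0.581,-11.62,FALSE
B36c,B,4-(CF3)-phenyl,4-(O-tBu)-phenyl,1.041,0.806,-10.05,TRUE
B36d,B,4-(CF3)-phenyl,4-Cyclobutoxyphenyl,1.387,1.041,-12.30,FALSE
B36e,B,4-(CF3)-phenyl,4-(Cyclopropylmethoxy)phenyl,0.886,1.034,-12.12,FALSE
B36f,B,4-(CF3)-phenyl,4-((Tetrahydro-2H-pyran-4-yl)oxy)-phenyl,0.237,0.998,-12.36,TRUE
B36g,B,4-(CF3)-phenyl,4-(Cyanomethoxy)-phenyl,-0.146,0.060,-12.02,TRUE
B45,B,4-(CF3)-phenyl,4-(Oxetan-3-yloxy)-phenyl,-0.041,0.300,-9.27,FALSE
B55a,B,2-(NMe2)-6-(CF3)-pyridin-3-yl,4-(F)-phenyl,0.000,-0.416,-10.65,TRUE
B55b,B,2-(Piperidin-1-yl)-6-(CF3)-pyridin-3-yl,4-(F)-phenyl,0.215,0.498,-9.96,FALSE
C11ak,C,"1,2,3,4-Tetrahydroquinolin-3-ol",OEt,0.854,0.321,-11.18,FALSE
C11al,C,"2-Oxo-1,2-dihydro-quinoline",OEt,0.658,-0.076,-10.76,FALSE
C11am,C,"3,4-Dihydroquinolin-2(1H)-one",OEt,0.602,0.139,-10.66,FALSE
C11an,C,Indolin-2-one,OEt,-0.114,0.224,-11.56,FALSE
C11ao,C,"2H-benzo[b][1,4]oxazin-3(4H)-one",OEt,-1.176,-0.786,-8.27,FALSE
C36h,C,"1,2,3,4-Tetrahydroquinolin-3-ol",O-iPr,0.796,0.593,-11.74,FALSE
C36i,C,"3,4-Dihydroquinolin-2(1H)-one",O-iPr,0.337,0.380,-10.38,FALSE
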