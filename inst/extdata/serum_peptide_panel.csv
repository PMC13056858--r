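observed_mass,annotated_sequence,length,accession,gene,protein
3241.91,NRGDSTFESKSYKMADEAGSEADHEGTHST,30,P02671,FGA,Fibrinogen alpha chain
3444.79,SETESRGSESGIFTNTKESSSHHPGIAEFPSR,32,P02671,FGA,Fibrinogen alpha chain
5904.80,SSSSSSSSSSSSSSSVHEPKMDALIIPVTMEVPCDSRGQRMWWAFLASSMVTFF,54,Q12791,KCNMA1,Calcium-activated potassium channel subunit alpha-1
5920.47,SCVLVLLVILNMMLFYKLWMLEYTTQTLTAWQGLRLQERLPQSQTEWAQ,53,Q3KR37,GRAMD1B,Protein Aster-B
1515.83,[P].TSAHGNVAEGETKPD.[P],15,P02790,HPX,Hemopexin
1568.81,[G].FKSHALQLNNRQI.[R],13,P0C0L4,C4A,Complement C4-A
1866.20,[L].FEKKSLEDKTERELL.[E],15,P00734,F2,Prothrombin
2991.70,R.MLLADQGQSWKEEVVTVETWQEGSLK.A,26,P09211,GSTP1,Glutathione S-transferase P
3381.09,LATVYVDVLKDSGRDYVSQFEGSALGKQLNL,31,P02647,APOA1,Apolipoprotein A-I
3770.10,A.GAAGSRMNFRPGVLSSRQLGLPGPPDVPDHAAYHPF.R,36,B2RMS9,ITIH4,Inter-alpha (Globulin) inhibitor H4
5337.66,[K].SSSYSKQFTSSTSYNRGDSTFESKSYKMADEAGSEADHEGTHSTKRGHA.[K],49,P02671,FGA,Fibrinogen alpha chain
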