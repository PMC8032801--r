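((Lec,Pm),((Cm,(Rt,Le)),(Lo,(((Aa,Ar),Aj),(Sf,((Ch,((Dr,((Lw,Pp),(Cc,(Sa,(Sg,Sr))))),(Ip,(Am,Pyn)))),((El,Ss),(Gm,((Bp,(Pem,(Ps,Sh))),((Hc,(To,Pa)),((Moa,((Lac,(Cs,(Po,Py))),(Stp,((Ac,(On,((Hb,Pun),(Mc,(Mz,Nb))))),(Ol,((Nf,(Km,(Fh,(Al,(Cn,Cv))))),((Xc,(Xh,Xm)),(Pf,(Pom,(Pl,Pr)))))))))),(Lb,((Mom,(Tn,(Tf,Tr))),(((Lc,Mim),(Dl,Ms)),(Nc,(Ga,(Cr,(Af,((Sea,Ses),(Sem,(Ser,Sn)))))))))))))))))))));
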