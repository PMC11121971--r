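id,name,smiles,frag,mclass,formula,avg_mass,mono_mass
AA,adipic acid,OC(=O)CCCCC(=O)O,C(=O)CCCCC(=O),diacid,C6H10O4,146.142,146.0579
FDCA,"2,5-furandicarboxylic acid",OC(=O)c1ccc(o1)C(=O)O,C(=O)c1ccc(o1)C(=O),diacid,C6H4O5,156.093,156.0059
TA,terephthalic acid,OC(=O)c1ccc(cc1)C(=O)O,C(=O)c1ccc(cc1)C(=O),diacid,C8H6O4,166.132,166.0266
BDO,"1,4-butanediol",OCCCCO,OCCCCO,diol,C4H10O2,90.122,90.0681
GLY,glycerol,OCC(O)CO,OCC(O)CO,polyol,C3H8O3,92.094,92.0473
ERY,erythritol,OCC(O)C(O)CO,OCC(O)C(O)CO,polyol,C4H10O4,122.120,122.0579
DAF,"2,5-bis(aminomethyl)furan",NCc1ccc(o1)CN,NCc1ccc(o1)CN,diamine,C6H10N2O,126.159,126.0793
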