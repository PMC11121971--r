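label,smiles,biodeg
AA-BDO-AA-BDO,C(CCCO)OC(=O)CCCCC(=O)OCCCCOC(=O)CCCCC(=O)O,50.23
AA-DAF-AA-DAF,NCc1ccc(o1)CNC(=O)CCCCC(=O)NCc1ccc(o1)CNC(=O)CCCCC(=O)N,1.59
AA-GLY-AA-GLY,C(C(O)CO)OC(=O)CCCCC(=O)OCC(O)COC(=O)CCCCC(=O)O,46.9
AA-GLY-AA-ERY,OCC(O)C(O)COC(=O)CCCCC(=O)OCC(O)COC(=O)CCCCC(=O)O,30.9
BDO-FDCA-BDO-AA,O=C(CCCCC(=O)O)OCCCCOC(=O)c1ccc(o1)C(=O)OCCCCO,26.81
BDO-FDCA-BDO-FDCA,OCCCCOC(=O)c1ccc(o1)C(=O)OCCCCOC(=O)c1ccc(o1)C(=O)O,15.22
BDO-TA-BDO-TA,OCCCCOC(=O)c1ccc(cc1)C(=O)OCCCCOC(=O)c1ccc(cc1)C(=O)O,37.92
FDCA-GLY-AA-GLY,OC(COC(=O)c1ccc(o1)C(=O)O)COC(=O)CCCCC(=O)OCC(O)CO,22.55
FDCA-GLY-FDCA-GLY,OCC(O)COC(=O)c1ccc(o1)C(=O)OCC(O)COC(=O)c1ccc(o1)C(=O)O,18.36
GLY-TA-GLY-TA,OCC(COC(=O)c1ccc(cc1)C(=O)OCC(COC(=O)c1ccc(cc1)C(=O)O)O)O,50.12
TA-BDO-AA-BDO,O=C(CCCCC(=O)O)OCCCCOC(=O)c1ccc(cc1)C(=O)OCCCCO,37.48
TA-GLY-AA-GLY,OC(COC(=O)c1ccc(cc1)C(=O)O)COC(=O)CCCCC(=O)OCC(O)CO,19.38
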