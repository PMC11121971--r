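sample,group,mn,mw,dispersity
BDO-FDCA,co-oligomer,635,742,1.16
BDO-TA,co-oligomer,694,838,1.20
BDO-AA,co-oligomer,683,729,1.06
GLY-FDCA,co-oligomer,551,936,1.69
GLY-TA,co-oligomer,960,1169,1.21
GLY-AA,co-oligomer,912,940,1.03
BDO-FDCA-AA,ter-oligomer,844,901,1.06
BDO-TA-AA,ter-oligomer,615,747,1.21
GLY-FDCA-AA,ter-oligomer,481,551,1.25
GLY-TA-AA,ter-oligomer,582,675,1.15
GLY-ERY-AA,ter-oligomer,845,1140,1.35
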