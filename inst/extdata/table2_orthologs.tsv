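# Human-mouse symbol pairs for the candidate-gene fixture, constructed by the
# standard case convention (human uppercase, mouse title case).
TOX2	Tox2
DUSP15	Dusp15
NKD2	Nkd2
CNGA1	Cnga1
PTK2B	Ptk2b
ESPN	Espn
SMOC2	Smoc2
ADAMTS16	Adamts16
FBLN2	Fbln2
NIPAL1	Nipal1
CYP26B1	Cyp26b1
SPRY4	Spry4
MYBL1	Mybl1
ETV4	Etv4
LGR5	Lgr5
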