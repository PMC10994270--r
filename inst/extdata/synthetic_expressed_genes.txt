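MET01
MET02
MET03
MET04
MET05
MET06
MET08
MET09
MET10
MET11
MET12
MET13
MET15
MET16
MET17
MET18
MET19
MET20
MET22
MET23
MET24
MET25
MET26
MET27
MET29
MET30
PRT01
PRT02
PRT03
PRT04
PRT06
PRT07
PRT08
PRT09
PRT10
PRT11
PRT13
PRT14
PRT15
PRT16
PRT17
PRT18
PRT20
PRT21
PRT22
PRT23
PRT24
PRT25
PRT27
PRT28
PRT29
PRT30
DNA01
DNA02
DNA04
DNA05
DNA06
DNA07
DNA08
DNA09
DNA11
DNA12
DNA13
DNA14
DNA15
DNA16
DNA18
DNA19
DNA20
DNA21
DNA22
DNA23
DNA25
DNA26
DNA27
DNA28
DNA29
DNA30
KIN02
KIN03
KIN04
KIN05
KIN06
KIN07
KIN09
KIN10
KIN11
KIN12
KIN13
KIN14
KIN16
KIN17
KIN18
KIN19
KIN20
KIN21
KIN23
KIN24
KIN25
KIN26
KIN27
KIN28
KIN30
EPI01
EPI02
EPI03
EPI04
EPI05
EPI07
EPI08
EPI09
EPI10
EPI11
EPI12
EPI14
EPI15
EPI16
EPI17
EPI18
EPI19
EPI21
EPI22
EPI23
EPI24
EPI25
EPI26
EPI28
EPI29
EPI30
MTU01
MTU02
MTU03
MTU05
MTU06
MTU07
MTU08
MTU09
MTU10
MTU12
MTU13
MTU14
MTU15
MTU16
MTU17
MTU19
MTU20
MTU21
MTU22
MTU23
MTU24
MTU26
MTU27
MTU28
MTU29
MTU30
VES01
VES03
VES04
VES05
VES06
VES07
VES08
VES10
VES11
VES12
VES13
VES14
VES15
VES17
VES18
VES19
VES20
VES21
VES22
VES24
VES25
ALZ01
ALZ02
ALZ03
ALZ04
ALZ06
ALZ07
ALZ08
ALZ09
ALZ10
ALZ11
ALZ13
ALZ14
ALZ15
ALZ16
ALZ17
ALZ18
ALZ20
BGD01
BGD02
BGD03
BGD04
BGD05
BGD07
BGD08
BGD09
BGD10
BGD11
BGD12
BGD14
BGD15
BGD16
BGD17
BGD18
BGD19
BGD21
BGD22
BGD23
BGD24
BGD25
BGD26
BGD28
BGD29
BGD30
BGD31
BGD32
BGD33
BGD35
BGD36
BGD37
BGD38
BGD39
BGD40
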