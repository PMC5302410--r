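# CARENET: cambium regulation gene network (30 nodes).
#
# Control nodes are external hormonal/peptidic inputs whose state is fixed
# for a whole simulation run; internal nodes evolve under the signed
# threshold update rule.
#
# PROVISIONAL WIRING: this edge list is transcribed from the prose
# description of the network blocks. The authoritative rule tables from the
# model's supplementary material were not available for transcription, so
# quantitative results that depend on the exact wiring are conditional on
# this file. The format is pure data: reconciling the wiring is a one-file
# edit with no code changes.
[nodes]
CK0    control
IAA0   control
BR     control
GA     control
TDIF   control
ETHL   control
CK     internal
AHK    internal
AHP    internal
AHP6   internal
RRA    internal
RRB    internal
IPT    internal
LOG    internal
CKX    internal
IAA    internal
ARF    internal
PIN    internal
ENDO   internal
TMO5   internal
LHW    internal
STM    internal
ERF    internal
WRKY   internal
BZR1   internal
BIN2   internal
PXY    internal
WOX4   internal
WOX14  internal
HB8    internal
[edges]
# cytokinin block
CK0  -> CK
IPT  -> CK
LOG  -> CK
CKX  -| CK
CK   -> AHK
AHK  -> AHP
AHP6 -| AHP
RRA  -| AHP
AHP  -> RRB
RRB  -> RRA
RRB  -> CKX
RRB  -> PIN
RRB  -> ERF
RRB  -> ENDO
TMO5 -> LOG
LHW  -> LOG
WRKY -> LOG
# auxin block
IAA0 -> IAA
GA   -> IAA
PIN  -| IAA
IAA  -> ARF
ARF  -> AHP6
ARF  -> CKX
ARF  -| IPT
ARF  -> TMO5
ARF  -> STM
ARF  -> PIN
ENDO -| PIN
STM  -| LHW
# ARF -> HB8 is the least prose-constrained choice for the HB8 regulators
ARF  -> HB8
# ethylene block
ETHL -> ERF
ERF  -> WOX4
# TDIF/PXY block
TDIF -> PXY
PXY  -> WOX4
PXY  -> WOX14
PXY  -> BIN2
# brassinosteroid / gibberellin block
BR   -| BIN2
BIN2 -| BZR1
BZR1 -> WRKY
GA   -> WRKY
WRKY -> ERF
# candidate edge not in the provisional list: WRKY -| CKX
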