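>JB6b_synthetic_standin 241-aa synthetic stand-in emulating DNAJB6b charge composition (not the real sequence)
YDFSYGPEFKTKGKFGKETKLFSSGFTNTCFFGGGFMRFFSDGYDKADPFGTFFDRMTPM
GTREKFMFKSSLKGFQSLPGKETFRKQTGRSSSKGSGTEGGKADDGRETEDRLTHLDESS
TTDEGDSKSSSDGKRACKDDHHKDYGSVSGDMGEFLKPTFPAGYPARTETKELAKAGASF
TGKSSTHEAGYKKYYGLDANFDSESPTFGFGGGSGSFGPDARPGFVGKKSVGSVMGGAGS
S
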