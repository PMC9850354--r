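# Neutral human milk oligosaccharide backbone structures, degree of
# polymerization (DP) 4 to 9. Condensed notation as in standards.tsv.
# Ids containing "syn" are constructed linkage variants (synthetic
# stand-ins completing an isomer family).
# id	name	structure
LNT	lacto-N-tetraose	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc
LNnT	lacto-N-neotetraose	Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-I	lacto-N-fucopentaose I	Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-II	lacto-N-fucopentaose II	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-III	lacto-N-fucopentaose III	Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-V	lacto-N-fucopentaose V	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNDFH-I	lacto-N-difucohexaose I	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc
LNnDFH-I	lacto-N-neodifucohexaose I	Fuc(a1-2)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
DFH-syn-2	difucohexaose, terminal+core fucosyl (synthetic)	Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNDFH-II	lacto-N-difucohexaose II	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNnDFH-II	lacto-N-neodifucohexaose II	Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNH	lacto-N-hexaose	Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
LNnH	lacto-N-neohexaose	Gal(b1-4)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
pLNH	para-lacto-N-hexaose	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
pLNnH	para-lacto-N-neohexaose	Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
MFLNH-I	monofucosyllacto-N-hexaose I	Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
MFLNH-III	monofucosyllacto-N-hexaose III	Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]Gal(b1-4)Glc
MFpLNH-IV	monofucosyl-para-lacto-N-hexaose IV	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
DFLNH-a	difucosyllacto-N-hexaose a	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
DFLNH-b	difucosyllacto-N-hexaose b	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]Gal(b1-4)Glc
DFpLNH-II	difucosyl-para-lacto-N-hexaose II	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
TFLNH	trifucosyllacto-N-hexaose	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]Gal(b1-4)Glc
TFpLNH	trifucosyl-para-lacto-N-hexaose	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
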