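# Purified milk-oligosaccharide standards and related reference
# structures, in condensed notation (rightmost residue = reducing end,
# branches bracketed before their attachment residue).
# Ids containing "syn" are constructed linkage variants that fill out
# the isomer families; they are synthetic stand-ins, not literature
# structures.
# id	name	structure
LNT	lacto-N-tetraose	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc
LNnT	lacto-N-neotetraose	Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-I	lacto-N-fucopentaose I	Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-II	lacto-N-fucopentaose II	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-III	lacto-N-fucopentaose III	Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
LNnFP-I	lacto-N-neofucopentaose I	Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
LNFP-V	lacto-N-fucopentaose V	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNDFH-I	lacto-N-difucohexaose I	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc
LNnDFH-I	lacto-N-neodifucohexaose I	Fuc(a1-2)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
DFH-syn-1	difucohexaose, terminal-difucosyl linkage variant (synthetic)	Fuc(a1-2)Gal(b1-3)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc
DFH-syn-2	difucohexaose, terminal+core fucosyl (synthetic)	Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
DFH-syn-3	difucohexaose, terminal+core fucosyl neo variant (synthetic)	Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNDFH-II	lacto-N-difucohexaose II	Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNnDFH-II	lacto-N-neodifucohexaose II	Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
DFH-syn-4	difucohexaose, internal+core fucosyl linkage variant (synthetic)	Gal(b1-3)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc
LNH	lacto-N-hexaose	Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
LNnH	lacto-N-neohexaose	Gal(b1-4)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc
pLNH	para-lacto-N-hexaose	Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
pLNnH	para-lacto-N-neohexaose	Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc
B-Tetra-T2	blood group B type-2 tetrasaccharide	Gal(a1-3)[Fuc(a1-2)]Gal(b1-4)GlcNAc
Globo-H-Hexa	Globo-H hexasaccharide	Fuc(a1-2)Gal(b1-3)GalNAc(b1-3)Gal(a1-4)Gal(b1-4)Glc
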