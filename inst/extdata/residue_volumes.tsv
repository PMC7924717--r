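# Mean amino-acid residue volumes (Angstrom^3), Zamyatnin-style consensus
# values; third column: residue electron counts (neutral form, with
# hydrogens) used for the optional electron-count SAXS form factors.
# resname	volume_A3	electrons
ALA	88.6	38
ARG	173.4	85
ASN	114.1	60
ASP	111.1	59
CYS	108.5	54
GLN	143.8	68
GLU	138.4	67
GLY	60.1	30
HIS	153.2	72
ILE	166.7	62
LEU	166.7	62
LYS	168.6	71
MET	162.9	70
PHE	189.9	78
PRO	112.7	52
SER	89.0	46
THR	116.1	54
TRP	227.8	98
TYR	193.6	86
VAL	140.0	54
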