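 *********************************************************************
 * TM-align: synthetic example output for parser tests               *
 *********************************************************************

Name of Chain_1: model.pdb
Name of Chain_2: native.pdb
Length of Chain_1:    5 residues
Length of Chain_2:    5 residues

Aligned length=    4, RMSD=   1.20, Seq_ID=n_identical/n_aligned= 0.750
TM-score= 0.60123 (if normalized by length of Chain_1)
TM-score= 0.65432 (if normalized by length of Chain_2)

(":" denotes residue pairs of d < 5.0 Angstrom, "." denotes other aligned residues)
ACDEF
::::
ACDE-
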