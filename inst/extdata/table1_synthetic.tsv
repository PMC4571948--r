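# ARBmotif candidate table v1 -- SYNTHETIC transcription of the published
# candidate summary. The six experimentally studied proteins carry their
# printed motif segments (SNAP25b decapeptide GVVASQPARV; CSPa PIVIQP; HTT
# IITEQP+R; CLIP3 QVTMTQP with its required upstream Gln; SNAP23 VSKQP
# completed with a synthetic Psi=Ile; MAP6 AIETQP). The motif regions of the
# 14 other named interactors and all flag assignments beyond the documented
# summary totals (20 final, 15 S-acylated, 10 zDHHC17 substrates, 8 zDHHC13
# interactors, 12 conserved, 14 not tested in the study) are synthetic,
# engineered only to reproduce those totals.
protein_id	sequence	region	s_acylated	dhhc17_substrate	dhhc13_interactor	golgi_or_pm_localized	homolog_of_qualified	motif_conserved_hfz	tested_in_this_study	disordered
SNAP25B		GVVASQPARV	TRUE	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
CSPA		PIVIQP	TRUE	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
HTT		IITEQPR	TRUE	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
CLIP3		QVTMTQP	TRUE	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
SNAP23		IVSKQP	TRUE	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
MAP6		AIETQP	TRUE	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE	TRUE
JNK1		PIVLQP	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE	TRUE
JNK2		PIVMQP	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE	TRUE
JNK3		PIVKQP	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE	FALSE	TRUE
ARHGAP21		AVRSQP	TRUE	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
NMNAT2		IIDKQP	TRUE	TRUE	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
SPRY1		AVRTQP	TRUE	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
SPRY2		AVHSQP	TRUE	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
SPRY3		AVRAQP	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE
SPRY4		AVNSQP	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
SPRED1		IVESQP	TRUE	TRUE	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
SPRED2		IVDSQP	TRUE	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
SREBF1		QITGSQP	TRUE	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
SREBF2		QVTSAQP	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE
MMP14		PVLAQP	FALSE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	TRUE
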