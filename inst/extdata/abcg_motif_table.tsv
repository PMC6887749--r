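# Consensus motifs of candidate phytohormone-transporter (ABCG-type)
# proteins: extended-alphabet consensus strings (B={N,D}, Z={Q,E}, J={I,L},
# X=any), with printed E-values carried as opaque text and MEME site counts.
motif_id	consensus	evalue	sites	width
1	VRGVSGGERKRVSIGNEJIINPSJLFLDEPTSGLDSTTALR	4.9e-1822	60	41
2	GFVTQDDVLFPHLTVEETLVFAALLRLPKTLSKEQKEKRVEEVISELGLE	1.1e-1875	60	50
3	EKTJLNGITGSVRPGEILALLGPSGSGKTTLLBALAGRLTQ	1.2e-1524	60	41
4	GKTVVTSIHQPSSRLFHLFDKLJLLSKGSLLYFGKASEAMV	1.5e-1397	60	41
5	WGFYPCFTALFTFPQERAMLTKERAAGMY	8.3e-1056	59	29
6	VKKIPVFIIWIRYLSFVYYTYRLLLKVQY	3.2e-924	58	29
7	WWZQFSILFQRGJKERRHEYFNWLRITQV	3.9e-814	41	29
8	QGLGLAIGATLMDLKRATTLASVTVLTFM	4.9e-674	46	29
9	RLSAYFLARTVVDLPLDLILPVAFLVITYWMAGLRPSAETF	2.3e-1088	58	41
10	GCSPLISMNPAEFLLDLANGN	5.6e-528	54	21
11	NGKPSPAVVHEYLVEAYETRVADEEKKKJMVPLPLDDELKLKVSISKREW	4.1e-705	21	50
12	KVSGSITYNGQTYSKFVKRRT	2.1e-485	59	21
13	ALJLGLLWWQSDSNN	1.9e-350	58	15
14	NNBPSPNSMVPTFANPFWIEMAVLAKRSMKNARRMPELFGI	3.9e-318	15	41
15	FGYRLLAYLALRRMK	5.3e-276	54	15
16	KPKFQTLPTLPJTLKFTDVTYKVILKGMR	1.8e-520	48	29
17	DEVPSGMALSRASSASLAFSFLFSGFTIP	4.9e-498	40	29
18	SSRELFRASPSRESLLMKRNSFIYKFKSAQL	1.0e-390	26	31
19	TGRTIVCTIHQPNIDIFEAFDELJLLKTGGRIIYSGPLGQHSSRVIEYFZ	2.9e-479	14	50
20	GISGGQKKRLTTAEMJIGPTKALFMDEITNGLDSSTAFQIVNSLQQLVHI	5.0e-469	14	50
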