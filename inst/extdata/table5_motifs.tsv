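section	gene	accession	residue	position	degree	provenance	window
MK	Gcd10p	P41814	K	436	1	findmod	RGKLHPLMTMKGGGGYLMWCH
MK	Pfk2p	P16862	K	180	1	literature	HSYTDLAYRMKTTDTYPSLPK
MK	Rpl23Ap	P04451	K	110	2	literature	GVIANPKGEMKGSAITGPVGK
MK	Rps17Ap	P02407	K	59	2	findmod	KIAGYTTHLMKRIQKGPVRGI
MK	Rvb2p	Q12464	K	412	1	findmod	LISVAQQIAMKRKNNTVEVED
MK	Ura7p	P28274	K	28	2	findmod	VLASSTGMLMKTLGLKVTSIK
MK	Uso1p	P25386	K	119	1	findmod	NGKYPSPLVMKQEKEQVDQFS
RGX_RXG	Ecm29p	P38737	R	1112	2	findmod	LAKSSALWSSRKGIAFGLGAI
RGX_RXG	Gus1p	P46655	R	371	2	findmod	IYRCNLTPHHRTGSTWKIYPT
RGX_RXG	Rpl27Bp	P38706	R	15	2	findmod	LKAGKVAVVVRGRYAGKKVVI
RGX_RXG	Rpl4Ap	P10664	R	84	2	findmod	IPRVGGGGTGRSGQGAFGNMC
RGX_RXG	Rps11Bp	P26781	R	67	2	findmod	KCPFTGLVSIRGKILTGTVVS
RGX_RXG	Tdh3p	P00359	R	11	2	findmod	MVRVAINGFGRIGRLVMRIAL
RGX_RXG	Tub2p	P02557	R	318	2	findmod	GRYLTVAAFFRGKVSVKEVED
WXXXR_GXXR	Cdc11p	P32458	R	35	2	findmod	VMIVGQSGSGRSTFINTLCGQ
WXXXR_GXXR	Ecm29p	P38737	R	542	1	findmod	ARLFNIWGTVRTNRFDIIEES
WXXXR_GXXR	Fks1p	P38631	R	946	1	findmod	TLRTRIWASLRSQTLYRTISG
WXXXR_GXXR	Fks1p	P38631	R	946	2	findmod	TLRTRIWASLRSQTLYRTISG
WXXXR_GXXR	Fks1p	P38631	R	1527	2	findmod	YHRNSWIGYVRMSRARITGFK
WXXXR_GXXR	Rpl4Ap	P10664	R	84	2	findmod	IPRVGGGGTGRSGQGAFGNMC
WXXXR_GXXR	Rpl7Ap	P05737	R	218	1	findmod	SNPSGGWGVPRKFKHFIQGGS
WXXXR_GXXR	Rsc30p	P38781	R	692	1	findmod	SIKSFSSGNNRFHSNGKEFLF
WXXXR_GXXR	Tdh3p	P00359	R	11	2	findmod	MVRVAINGFGRIGRLVMRIAL
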