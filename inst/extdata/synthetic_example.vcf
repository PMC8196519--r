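##fileformat=VCFv4.2
##contig=<ID=chr1,length=500000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	5428	.	C	T	.	PASS	.
chr1	13599	.	A	T	.	PASS	.
chr1	21526	.	T	C	.	PASS	.
chr1	21919	.	A	T	.	PASS	.
chr1	25885	.	A	C	.	PASS	.
chr1	102683	.	T	A	.	PASS	.
chr1	104145	.	G	C	.	PASS	.
chr1	104792	.	G	C	.	PASS	.
chr1	121997	.	A	G	.	PASS	.
chr1	126491	.	A	T	.	PASS	.
chr1	128911	.	T	A	.	PASS	.
chr1	150077	.	C	G	.	PASS	.
chr1	151141	.	G	A	.	PASS	.
chr1	154316	.	A	T	.	PASS	.
chr1	161360	.	A	T	.	PASS	.
chr1	163657	.	T	A	.	PASS	.
chr1	165813	.	C	A	.	PASS	.
chr1	167390	.	C	T	.	PASS	.
chr1	183482	.	A	T	.	PASS	.
chr1	230680	.	G	A	.	PASS	.
chr1	230690	.	T	G	.	PASS	.
chr1	230720	.	A	T	.	PASS	.
chr1	230914	.	G	T	.	PASS	.
chr1	231104	.	A	C	.	PASS	.
chr1	231137	.	T	A	.	PASS	.
chr1	231189	.	A	T	.	PASS	.
chr1	231243	.	T	C	.	PASS	.
chr1	231266	.	C	A	.	PASS	.
chr1	231468	.	T	G	.	PASS	.
chr1	231572	.	A	G	.	PASS	.
chr1	236402	.	G	T	.	PASS	.
chr1	236795	.	A	T	.	PASS	.
chr1	236954	.	T	G	.	PASS	.
chr1	237123	.	A	C	.	PASS	.
chr1	237136	.	A	T	.	PASS	.
chr1	237194	.	T	A	.	PASS	.
chr1	237227	.	T	C	.	PASS	.
chr1	237230	.	A	G	.	PASS	.
chr1	239900	.	A	G	.	PASS	.
chr1	253611	.	G	A	.	PASS	.
chr1	266815	.	A	C	.	PASS	.
chr1	291141	.	T	A	.	PASS	.
chr1	298326	.	G	C	.	PASS	.
chr1	304785	.	C	A	.	PASS	.
chr1	313696	.	T	C	.	PASS	.
chr1	314795	.	T	C	.	PASS	.
chr1	334709	.	C	G	.	PASS	.
chr1	338122	.	C	G	.	PASS	.
chr1	338862	.	A	T	.	PASS	.
chr1	357343	.	T	C	.	PASS	.
chr1	364549	.	C	G	.	PASS	.
chr1	367904	.	G	C	.	PASS	.
chr1	407234	.	A	C	.	PASS	.
chr1	420704	.	A	G	.	PASS	.
chr1	423940	.	C	T	.	PASS	.
chr1	425933	.	G	A	.	PASS	.
chr1	427880	.	A	C	.	PASS	.
chr1	467153	.	G	C	.	PASS	.
chr1	476817	.	C	A	.	PASS	.
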