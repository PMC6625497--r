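# Bundled subset of the EDAM ontology (format and data axes), tabular
# dialect: term_id<TAB>label<TAB>parent_id[,parent_id...]
# is-a parents only; roots have an empty third column.
format_1915	Format
format_2330	Textual format	format_1915
format_2333	Binary format	format_1915
format_2044	Sequence record format	format_1915
format_2055	Sequence assembly format	format_1915
format_2920	Alignment format	format_1915
format_2921	Sequence alignment format	format_2920
format_2032	Sequence range format	format_1915
format_2205	Sequence feature annotation format	format_1915
format_3326	Data index format	format_1915
format_2350	Ontology format	format_1915
format_1929	FASTA	format_2044,format_2330
format_1930	FASTQ	format_2044,format_2330
format_1931	FASTQ illumina	format_1930
format_1932	FASTQ sanger	format_1930
format_1933	FASTQ solexa	format_1930
format_2572	BAM	format_2921,format_2333
format_2573	SAM	format_2921,format_2330
format_3462	CRAM	format_2921,format_2333
format_3016	VCF	format_2330
format_3020	BCF	format_2333
format_3003	BED	format_2032,format_2330
format_3004	bigBed	format_2032,format_2333
format_1975	GFF3	format_2205,format_2330
format_2306	GTF	format_2205,format_2330
format_3005	WIG	format_2032,format_2330
format_3006	bigWig	format_2032,format_2333
format_3009	GFF2	format_2205,format_2330
format_3475	TSV	format_2330
format_3752	CSV	format_2330
format_3464	JSON	format_2330
format_3750	YAML	format_2330
format_2546	FASTA like	format_2330
format_1919	Sequence record full format	format_2044
format_3327	BAI	format_3326,format_2333
format_3616	tabix	format_3326,format_2333
format_3484	ebwt	format_3326,format_2333
format_2195	Ontology term format	format_2350
format_3262	OWL XML	format_2350
format_2549	OBO	format_2350
data_0006	Data
data_2044	Sequence	data_0006
data_2976	Protein sequence	data_2044
data_2977	Nucleic acid sequence	data_2044
data_0849	Sequence record	data_0006
data_1234	Sequence set nucleic acid	data_0006
data_0863	Sequence alignment	data_0006
data_1383	Nucleic acid sequence alignment	data_0863
data_3498	Sequence variations	data_0006
data_0945	Peptide identification	data_0006
data_2012	Sequence coordinates	data_0006
data_1255	Sequence features	data_0006
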