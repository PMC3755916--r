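# synthetic shared-segment file (not real data): plausible IBD segments
# for a moderately related pair on the five-length model human genome;
# coordinates in cM, 0-based half-open, chromosome ids as in
# chromosome_table(genome_model("human5"))
chrom	start_cM	end_cM
2	31.4	58.9
4	0	22.7
7	101.3	125.0
9	66.2	91.8
12	140.1	175.0
15	12.6	31.0
19	180.4	210.0
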