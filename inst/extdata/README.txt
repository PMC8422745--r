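Drop-in location for the reconstructed published survey (optional).

To verify the package against the full 326-individual COI survey, rebuild
that dataset from its GenBank haplotype deposits (MT884019-MT884059) plus
the survey's haplotype-by-population count table (expand with
coipopgen::expand_haplotype_table), and place here before installing:

  reconstructed_326.fasta        aligned 674-bp sequences, 326 records
  reconstructed_326_popmap.csv   sample_id,population (PJ,SL,AS,DL,SY,SH,JN)

The final acceptance test picks these up via system.file(); without them
it reports the check as failed. No data are bundled: the sequences are
third-party deposits and the package must build offline.
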