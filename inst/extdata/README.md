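# External data drop-in

The original study's supplementary files are distributed as a
spreadsheet (polymorphic-position table) and a PDF (multilocus PHYLIP
input), neither of which this package parses directly. To run the full
real-data checks, re-export them to plain text and place them here
(or in the installed package's `extdata/` directory) as:

- `study_sites.tsv` — the polymorphic-position table in the
  package's site-table dialect: tab-separated with header
  `locus_id  pos  allele_anc  allele_der  F  S  A  M  O` (optional
  `A2`), diploid genotypes coded 0/1/2 copies of `allele_der`, the
  mastodon column `O` coded 0/1, missing calls as `.`.
- `study_loci.phy` — the multilocus alignment as concatenated
  sequential-PHYLIP blocks (`<n> <len>` header, then one labelled
  sequence per line).

`read_site_table()` and `read_phylip_multilocus()` document the exact
dialects. Without these files the corresponding acceptance tests report
failure and all simulator-based checks still run.
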