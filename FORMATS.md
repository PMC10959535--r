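# File formats

All tables are tab-separated with a header row, preceded by metadata
lines of the form `# key=value` (always including `tool`; pipeline
outputs add `config_hash` and `seed`). `readTsv()` skips the metadata;
`tsvMeta()` recovers it.

## Inputs

* **Genome FASTA** — multi-record, wrapped lines; alphabet A/C/G/T/N.
* **Annotation GTF** — `exon` and `CDS` features with `gene_id` and
  `transcript_id` attributes; 1-based inclusive coordinates.
* **Domain BED** (`readDomains`) — BED dialect in *protein*
  coordinates: column 1 carries the transcript id, columns 2-3 the
  0-based half-open amino-acid interval, column 4 the domain name.
* **Event table** (`readEvents`) — `event_id`, `type` (SE, RI, A5SS,
  A3SS, MXE), `gene_id`, `transcript_id`, `chrom`, `strand`,
  `alt_start`, `alt_end`, `alt_start2`, `alt_end2` (NA unless MXE;
  annotated exon first), `len_inclusion`, `len_skipping`.
* **Junction counts** (long format, `psiMatrix`) — `event_id`, `type`,
  `sample`, `inclusion_count`, `skipping_count`, `len_inclusion`,
  `len_skipping`.
* **Matrix TSV** (`readMatrixTsv`) — feature id in column 1, sample
  ids in the header (counts, normalized expression, beta values,
  clock expression).
* **Sample groups** — `sample`, `group`.
* **GMT** — standard gene-set format: name, description, members,
  tab-separated.
* **Clock model** (`readClockModel`) — `gene`, `weight`,
  `training_mean`, `training_sd`, `imputation_value` (log2 scale),
  with the intercept in a `# intercept=` metadata line.
* **Probe state map** (`readStateMap`) — either `probe`/`state`
  columns, or BED with the state in column 4.
* **Pipeline config** — YAML overriding `defaultConfig()` entries.

## Outputs

* **Psi matrix** — events × samples, `NA` below the coverage floor.
* **Differential splicing** — `event_id`, `type`, `mean_control`,
  `mean_treated`, `delta_psi`, `p_value`, `tested`, `fdr`, `selected`.
* **Consequence calls** — `event_id`, `transcript_id`, `alt_form`,
  `category`, `altered_aa_start`, `altered_aa_end`, `new_stop_aa`,
  `damaging`.
* **Damage report** — `n_events`, `n_damaging`, `proportion`
  (differential mode) or one row per `sample` (standing mode).
* **DE table** — `gene`, `lfc`, `pv`, `fdr`.
* **Enrichment table** — `set`, `size`, `es`, `nes`, `p_value`, `fdr`,
  `significant`, `error`; association tables add `condition` and
  `stars`.
* **tAge predictions** — `sample`, `tAge`, `n_imputed`,
  `fully_imputed`; contrasts: `stratum`, `treatment`, `effect`,
  `p_value`.
* **DMP table** — `probe`, `lfcM`, `pv`, `fdr`, `direction`,
  `selected`.
* **State enrichment** — `state`, `direction`, `n_state`, `n_dmp`,
  `overlap`, `odds_ratio`, `p_value`, `adj_p`, `signed_log10_adj_p`.
* **manifest.json** — tool version, config hash, seed, documented
  model substitutions, and per-stage MD5 checksums of every output.
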