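# Table schemas

All tables are UTF-8 delimited text (tab by default; comma autodetected
from the header), LF line endings, fixed column order as listed.

## Run table (long format, one row per run x detected protein)

| column     | type    | notes                                        |
|------------|---------|----------------------------------------------|
| run_id     | string  | unique per purification run                  |
| bait_id    | string  | protein id, or `CONTROL:<name>` for mocks    |
| replicate  | integer | biological replicate index, >= 1             |
| condition  | string  | e.g. untreated, OA, low_density, t30         |
| protein_id | string  | must exist in the protein table              |
| spc        | number  | spectral count, >= 0                         |
| intensities| string  | `;`-joined positive precursor intensities    |

## Protein table

| column     | type    | notes                                        |
|------------|---------|----------------------------------------------|
| protein_id | string  | unique                                       |
| length     | integer | amino acids, >= 1                            |
| is_bait    | logical | optional; inferred from runs when absent     |

## Reference PPI table

| column         | type    | notes                                    |
|----------------|---------|------------------------------------------|
| protein_a      | string  | unordered pair, canonicalized on read    |
| protein_b      | string  |                                          |
| n_publications | integer | >= 1; duplicates merged by maximum       |

## Network edge table (written by `write_network`)

Columns `bait`, `prey` followed by the edge attributes present
(`xbar`, `enrichment`, `wd`, `wdn`, `rescued`, `module`, `wdn_reverse`).
SIF rows are `bait<TAB>pp<TAB>prey`; GraphML carries all edge attributes.
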