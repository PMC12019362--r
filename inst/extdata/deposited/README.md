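# Deposited CpaF hexamer models

The deposited-structure validation tests read the CpaF atomic models from
this directory. Coordinate files are not redistributed with the package;
download them from the Protein Data Bank and place them here as
`<ID>.cif` (or `.cif.gz` / `.pdb`):

- 9E24 (closed, apo)
- 9E25 (compact, apo dataset)
- 9E26 (compact, under-saturated ATP/ADP)
- 9E27 (expanded, under-saturated ATP/ADP)
- 9E29 (expanded, saturated ATP)

e.g. `curl -O https://files.rcsb.org/download/9E26.cif`

Without these files the deposited-structure acceptance tests fail with a
message pointing here; the synthetic-fixture test suite is unaffected.
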