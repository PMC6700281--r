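# Modifier-haplotype tag-SNP rule sets for the three DNA-maintenance loci
# (MSH3/DHFR on chr 5, FAN1 on chr 15, LIG1 on chr 19). Rules are evaluated
# in order; a SNP takes the first matching label. "cmp" comparators are
# strict. "conditional" entries refer to the p-value of the analysis
# conditioned on the named SNP. 15AM3 requires the signal to survive
# conditioning on either FAN1 marker, i.e. to stay below threshold in both
# conditional analyses. 15AM4 has no stated onset direction.
- label: 5AM1
  direction: hastened
  marginal: {cmp: "<", p: 1.0e-5}
  conditional:
    - {snp: rs701383, cmp: ">", p: 1.0e-5}
- label: 5AM2
  direction: delayed
  maf: {lt: 0.05}
  marginal: {cmp: "<", p: 1.0e-3}
  conditional:
    - {snp: rs701383, cmp: "<", p: 1.0e-3}
- label: 5AM3
  direction: delayed
  maf: {ge: 0.20, le: 0.35}
  marginal: {cmp: "<", p: 1.0e-3}
  conditional:
    - {snp: rs701383, cmp: ">", p: 1.0e-3}
- label: 15AM1
  direction: hastened
  maf: {lt: 0.05}
  marginal: {cmp: "<", p: 5.0e-8}
  conditional:
    - {snp: rs150393409, cmp: ">", p: 5.0e-8}
    - {snp: rs35811129, cmp: "<", p: 5.0e-8}
- label: 15AM2
  direction: delayed
  maf: {gt: 0.20}
  marginal: {cmp: "<", p: 5.0e-8}
  conditional:
    - {snp: rs150393409, cmp: "<", p: 5.0e-8}
    - {snp: rs35811129, cmp: ">", p: 5.0e-8}
- label: 15AM3
  direction: hastened
  maf: {lt: 0.03}
  marginal: {cmp: "<", p: 1.0e-5}
  conditional:
    - {snp: rs150393409, cmp: "<", p: 1.0e-5}
    - {snp: rs35811129, cmp: "<", p: 1.0e-5}
- label: 15AM4
  maf: {gt: 0.30}
  marginal: {cmp: "<", p: 1.0e-5}
  conditional:
    - {snp: rs150393409, cmp: "<", p: 5.0e-8}
- label: 19AM1
  direction: delayed
  marginal: {cmp: "<", p: 1.0e-4}
  conditional:
    - {snp: rs274883, cmp: ">", p: 1.0e-2}
- label: 19AM2
  direction: hastened
  maf: {gt: 0.30}
  marginal: {cmp: "<", p: 1.0e-5}
  conditional:
    - {snp: rs3730945, cmp: ">", p: 1.0e-5}
- label: 19AM3
  direction: delayed
  maf: {lt: 0.02}
  marginal: {cmp: "<", p: 1.0e-2}
  conditional:
    - {snp: rs145821638, cmp: ">", p: 1.0e-2}
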