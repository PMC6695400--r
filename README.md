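# semadimer

Comparative structural analysis of semaphorin ectodomains and their
dimerization, in R.

Semaphorins are axon-guidance ligands whose sema domains (seven-bladed
β-propellers) signal by dimerizing plexin receptors. Whether a given
semaphorin is a covalent dimer, a non-covalent dimer or a monomer — and which
structural elements hold a dimer together — is decided by a small set of
measurable quantities: the buried surface area of the dimer interface and its
partition over domains and N-glycans, the presence of an interchain
disulfide bond, sequence/structure divergence between paralogues, the
chemistry of the receptor-binding site, the apparent K<sub>d</sub> of the
plexin interaction, and the molar mass observed in solution. `semadimer`
implements each of these measurements as a tested, seed-reproducible
function, plus synthetic generators so the whole pipeline can be validated
without downloading anything.

## What is computed

| Quantity | Core definition | Function |
|---|---|---|
| Solvent-accessible area | Shrake–Rupley, Fibonacci lattice, probe 1.4 Å | `sasa()` |
| Buried surface | ΔASA summed over both partners: `SASA(A)+SASA(B)−SASA(A∪B)` | `buried_surface()`, `component_contribution()` |
| Glycan grouping | sugars walked from Asn ND2 through O–C links | `assign_glycans()` |
| Disulfides / covalent dimer | Cys SG–SG ≤ 2.3 Å, interchain scope | `find_disulfides()`, `covalent_dimer_call()` |
| Core rmsd | Kabsch fit, iterative trimming at `max(2·rmsd, 3.5 Å)` | `match_and_superpose()` |
| Hinge angle | anchor fit, then `θ = acos((tr(R)−1)/2)` on the mobile domain | `hinge_angle()` |
| Ensemble RMSF | per-residue fluctuation about the fitted mean structure | `ensemble_rmsf()` |
| Alignment / identity / sequons | Gotoh affine-gap DP, BLOSUM62; N-X(≠P)-[S/T] scan | `global_align()`, `progressive_msa()`, `sequon_scan()` |
| Specificity hot-spots | interface transfer by superposition; class-uniform chemistry swaps | `transfer_interface()`, `call_hotspots()` |
| Structure tree | `D = rmsd_core / coverage`, NJ or UPGMA, Newick | `build_distance_matrix()`, `nj_tree()`, `upgma_tree()` |
| Apparent K<sub>d</sub> | exact 1:1 depletion isotherm `f = ((R+L+K_d)−√((R+L+K_d)²−4RL))/(2R)`, bootstrap s.d. | `fit_kd()` |
| Oligomeric state | `argmin_n |m_obs − n·m_theor|/(n·m_theor)`, 15% tolerance | `theoretical_mass()`, `assign_oligomer()` |

Structures are read and written as PDB or mmCIF (`read_structure()`,
`write_structure()`), with author numbering preserved everywhere and a small
selection language (`"chain A and resi 120-130"`, `"kind glycan"`, ...) for
grouping. `run_dimer_report()`, `run_specificity_report()` and
`run_tree_report()` bundle the stages into machine-readable reports that
embed their full configuration.

## Worked example

```r
library(semadimer)

# a C2-symmetric dimer with a planted interchain disulfide and a planted
# three-sugar glycan contacting the partner chain
domain <- make_toy_domain(40, seed = 7)
dimer  <- make_c2_dimer(domain, plant_ss = TRUE, plant_glycan = TRUE, seed = 3)

run_dimer_report(dimer, components = list(glycans = "kind glycan"),
                 n_points = 480)
#> dimer_report [toy_40_7_c2]
#>   buried surface: 472.2 A^2
#>   glycans contribution: 21.5%
#>   contacts: 43 typed pairs
#>   covalent-dimer verdict: covalent_dimer

# a titration generated at a 25 nM preset and refitted
tt  <- make_titration(kd = 25e-9, noise_cv = 0.02, seed = 11)
fit_kd(tt, n_bootstrap = 200, seed = 1)
#> kd_fit: apparent Kd 2.51e-08 M (bootstrap s.d. 1.9e-09 M, n = 200)

# oligomeric state from a measured molar mass
assign_oligomer(75, 0.3, m_theor_monomer = 70)
#> oligomer_assignment: 75.0 +/- 0.3 kDa observed vs 70.0 kDa expected (n = 1)
#>   relative deviation 0.071 -> monomer
```

Reading the numbers: the dimer buries 472 Å² of surface (both chains
summed), of which the planted glycans contribute 21.5%; the interchain S–S
bond makes the covalent-dimer verdict positive. The K<sub>d</sub> fit
recovers the 25 nM generating value within one bootstrap s.d. A 75 kDa
light-scattering mass against a 70 kDa theoretical monomer deviates by 7%,
comfortably inside the 15% assignment tolerance, so the species is called a
monomer.

## Documentation

Function documentation lives in the roxygen comments in `R/`; the methods
vignette (`vignettes/semadimer-methods.Rmd`) explains the models,
parameter defaults, generator design and known limitations.
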