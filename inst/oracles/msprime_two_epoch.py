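"""Independent coalescent oracle for simulator cross-validation.

Simulates a single-deme (NE-only) history with msprime: exponential growth
from the bottleneck size N_D (at T_dom generations BP) to the modern size,
then a constant ancestral size beyond T_dom; haploid samples at the present;
finite-site JC69 mutations on L discrete sites.  Writes a TSV of per-replicate
segregating sites S and mean pairwise differences pi.

Usage: python msprime_two_epoch.py N_D N_MOD N_ANC T_DOM N_SAMP L MU_SITE REPS SEED OUT
"""
import sys

import msprime
import numpy as np


def main():
    (nd, nmod, nanc, tdom, nsamp, L, mu, reps, seed) = (
        float(sys.argv[1]), float(sys.argv[2]), float(sys.argv[3]),
        float(sys.argv[4]), int(sys.argv[5]), int(sys.argv[6]),
        float(sys.argv[7]), int(sys.argv[8]), int(sys.argv[9]))
    out = sys.argv[10]

    growth = np.log(nmod / nd) / tdom  # size(t) = nmod * exp(-growth t)
    dem = msprime.Demography()
    dem.add_population(name="NE", initial_size=nmod, growth_rate=growth)
    dem.add_population_parameters_change(time=tdom, population="NE",
                                         initial_size=nanc, growth_rate=0)

    anc = msprime.sim_ancestry(
        samples={"NE": nsamp}, demography=dem, ploidy=1,
        sequence_length=L, recombination_rate=0,
        num_replicates=reps, random_seed=seed)

    rows = []
    rng = np.random.default_rng(seed)
    for ts in anc:
        mts = msprime.sim_mutations(
            ts, rate=mu, model=msprime.JC69(),
            random_seed=int(rng.integers(1, 2**31 - 1)))
        gm = mts.genotype_matrix()  # sites x samples
        seg = int(np.sum([len(np.unique(row)) > 1 for row in gm]))
        pi = float(mts.diversity(mode="site", span_normalise=False))
        rows.append((seg, pi))

    with open(out, "w") as fh:
        fh.write("S\tpi\n")
        for s, p in rows:
            fh.write(f"{s}\t{p}\n")


if __name__ == "__main__":
    main()
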