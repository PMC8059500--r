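"""Independent windowed-statistics oracle based on msprime/tskit.

Simulates one two-population locus (diploid individuals), writes the
diploid derived-allele dosage matrix together with tskit's site-mode
nucleotide diversity (per population), Tajima's D (per population) and
between-population divergence, all computed on the full locus. Config
JSON: {n_dip1, n_dip2, N, T_split, L, mu, seed}.

Usage: python msprime_window_stats.py config.json out.json
"""
import json
import sys

import msprime
import numpy as np


def main(cfg_path, out_path):
    cfg = json.load(open(cfg_path))
    dem = msprime.Demography()
    dem.add_population(name="p1", initial_size=cfg["N"])
    dem.add_population(name="p2", initial_size=cfg["N"])
    dem.add_population(name="anc", initial_size=cfg["N"])
    dem.add_population_split(time=cfg["T_split"], derived=["p1", "p2"],
                             ancestral="anc")
    ts = msprime.sim_ancestry(
        samples={"p1": cfg["n_dip1"], "p2": cfg["n_dip2"]}, ploidy=2,
        demography=dem, sequence_length=cfg["L"], recombination_rate=0,
        random_seed=cfg["seed"])
    mts = msprime.sim_mutations(ts, rate=cfg["mu"], discrete_genome=False,
                                random_seed=cfg["seed"] + 1)
    s1 = mts.samples(population=0)
    s2 = mts.samples(population=1)
    G = mts.genotype_matrix()  # sites x haploid samples
    # collapse haplotypes into diploid dosages (individuals are
    # consecutive sample pairs)
    dos = G[:, ::2] + G[:, 1::2]
    out = {
        "dosage": dos.tolist(),
        "n_sites": int(G.shape[0]),
        "pi1": float(mts.diversity(s1, mode="site")),
        "pi2": float(mts.diversity(s2, mode="site")),
        "td1": float(mts.Tajimas_D(s1, mode="site")),
        "td2": float(mts.Tajimas_D(s2, mode="site")),
        "dxy": float(mts.divergence([s1, s2], mode="site")),
        "L": cfg["L"],
    }
    json.dump(out, open(out_path, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
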