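"""Independent joint-SFS oracle based on msprime/tskit.

Reads a JSON config {n1, n2, N1, N2, N_anc, T_split, epochs: [[t0, t1,
m12, m21], ...], mu, L, n_loci, seed} describing a two-deme divergence
model (haploid sample sizes, diploid population sizes, times in
generations, backward per-lineage migration rates), simulates `n_loci`
independent non-recombining loci, and writes a JSON object with the
per-cell mean and standard deviation of the unfolded joint site-frequency
spectrum across loci (row-major, rows = derived count in population 1).

Usage: python msprime_joint_sfs.py config.json out.json
"""
import json
import sys

import msprime
import numpy as np


def build_demography(cfg):
    dem = msprime.Demography()
    dem.add_population(name="p1", initial_size=cfg["N1"])
    dem.add_population(name="p2", initial_size=cfg["N2"])
    dem.add_population(name="anc", initial_size=cfg["N_anc"])
    events = []
    for t0, t1, m12, m21 in cfg.get("epochs", []):
        if m12 > 0:
            events.append((t0, "p1", "p2", m12))
            if t1 < cfg["T_split"]:
                events.append((t1, "p1", "p2", 0.0))
        if m21 > 0:
            events.append((t0, "p2", "p1", m21))
            if t1 < cfg["T_split"]:
                events.append((t1, "p2", "p1", 0.0))
    for t, src, dst, rate in sorted(events, key=lambda e: e[0]):
        dem.add_migration_rate_change(time=t, source=src, dest=dst, rate=rate)
    dem.add_population_split(time=cfg["T_split"], derived=["p1", "p2"],
                             ancestral="anc")
    dem.sort_events()
    return dem


def main(cfg_path, out_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    dem = build_demography(cfg)
    n1, n2 = cfg["n1"], cfg["n2"]
    if n1 % 2 or n2 % 2:
        raise SystemExit("haploid sample sizes must be even")
    # diploid sampling keeps msprime on the 1/(2N) pair-coalescence
    # timescale matching diploid effective sizes
    reps = msprime.sim_ancestry(
        samples={"p1": n1 // 2, "p2": n2 // 2}, ploidy=2, demography=dem,
        sequence_length=cfg["L"], recombination_rate=0,
        num_replicates=cfg["n_loci"], random_seed=cfg["seed"])
    shape = (n1 + 1) * (n2 + 1)
    tot = np.zeros(shape)
    tot2 = np.zeros(shape)
    rng = np.random.default_rng(cfg["seed"])
    for ts in reps:
        mts = msprime.sim_mutations(
            ts, rate=cfg["mu"], discrete_genome=False,
            random_seed=int(rng.integers(1, 2**31)))
        afs = mts.allele_frequency_spectrum(
            sample_sets=[mts.samples(population=0),
                         mts.samples(population=1)],
            polarised=True, span_normalise=False, mode="site")
        v = afs.reshape(-1)
        tot += v
        tot2 += v * v
    n = cfg["n_loci"]
    mean = tot / n
    sd = np.sqrt(np.maximum(tot2 / n - mean**2, 0) * n / max(n - 1, 1))
    json.dump({"mean": mean.tolist(), "sd": sd.tolist(), "n": n},
              open(out_path, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
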