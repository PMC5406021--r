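// Core simulation machinery: structured serial-sample coalescent,
// generalized stepwise (microsatellite) and HKY (sequence) mutation,
// conditional equilibrium-heterozygosity simulation for the
// heterozygosity-excess bottleneck test, and summary-statistic kernels
// shared by the ABC reference-table builder.
//
// All randomness goes through R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <unordered_map>
#include <string>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Structured coalescent
// ---------------------------------------------------------------------------

// Backward-in-time structured coalescent with serial samples and timed
// demographic events.
//
// Events (sorted by time ascending, time in generations before present):
//   type 0: ne_change  -- pop's Ne becomes ev_ne[i] for all older times
//   type 1: merge      -- all lineages in ev_pop move to ev_dest (split,
//                         viewed backward); ev_pop is dead afterwards
//   type 2: admixture  -- each lineage in ev_pop independently moves to
//                         ev_dest with prob ev_prob, else to ev_dest2
//
// Pair-coalescence rate within pop i with k lineages: k(k-1)/2 / (ne_scale *
// Ne_i) per generation. ne_scale = 2 for autosomal diploid (2N gene copies),
// 1 for a haploid locus with Ne copies, 0.25 for mtDNA at Ne/4.
//
// Tips are numbered 0..(sum(samp_n)-1) in the order the sample blocks are
// given, regardless of sampling time.
// [[Rcpp::export]]
List sim_tree_cpp(int npop, NumericVector ne0, double ne_scale,
                  NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_pop, IntegerVector ev_dest,
                  IntegerVector ev_dest2, NumericVector ev_prob,
                  NumericVector ev_ne,
                  IntegerVector samp_pop, NumericVector samp_time,
                  IntegerVector samp_n) {
  const int nev = ev_time.size();
  const int nblock = samp_pop.size();
  int ntips = 0;
  for (int b = 0; b < nblock; ++b) ntips += samp_n[b];
  if (ntips < 1) stop("no samples requested");

  const int nnode_max = 2 * ntips;     // tips + at most ntips-1 internal
  std::vector<int> parent(nnode_max, -1);
  std::vector<double> ntime(nnode_max, 0.0);

  // sample blocks with fixed tip id ranges, then process them time-sorted
  std::vector<int> border(nblock);
  for (int b = 0; b < nblock; ++b) border[b] = b;
  std::stable_sort(border.begin(), border.end(), [&](int a, int b2) {
    return samp_time[a] < samp_time[b2];
  });
  std::vector<int> bstart(nblock);
  {
    int acc = 0;
    for (int b = 0; b < nblock; ++b) { bstart[b] = acc; acc += samp_n[b]; }
  }

  std::vector<std::vector<int> > act(npop);
  std::vector<double> ne(ne0.begin(), ne0.end());
  std::vector<bool> dead(npop, false);

  int next_node = ntips;
  int iev = 0, iblock = 0, nactive = 0, npending = ntips;
  double t = 0.0;

  while (true) {
    if (nactive <= 1 && npending == 0) break;

    // total coalescence rate
    double R = 0.0;
    for (int p = 0; p < npop; ++p) {
      const double k = (double)act[p].size();
      if (k >= 2.0) {
        if (ne[p] <= 0.0) stop("non-positive Ne in an occupied population");
        R += k * (k - 1.0) / 2.0 / (ne_scale * ne[p]);
      }
    }

    double t_sched = R_PosInf;
    bool sched_is_event = false;
    if (iev < nev) { t_sched = ev_time[iev]; sched_is_event = true; }
    if (iblock < nblock && samp_time[border[iblock]] < t_sched) {
      t_sched = samp_time[border[iblock]];
      sched_is_event = false;
    }

    double dt = (R > 0.0) ? exp_rand() / R : R_PosInf;

    if (t + dt < t_sched) {
      // coalescence
      t += dt;
      double u = unif_rand() * R, acc = 0.0;
      int cpop = -1;
      for (int p = 0; p < npop; ++p) {
        const double k = (double)act[p].size();
        if (k >= 2.0) {
          acc += k * (k - 1.0) / 2.0 / (ne_scale * ne[p]);
          if (u <= acc) { cpop = p; break; }
        }
      }
      if (cpop < 0) cpop = npop - 1;  // numerical guard
      std::vector<int> &v = act[cpop];
      const int k = (int)v.size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      const int a = v[i], b = v[j];
      if (next_node >= nnode_max) stop("node overflow");
      parent[a] = next_node; parent[b] = next_node;
      ntime[next_node] = t;
      // remove the two, add the parent
      if (i > j) std::swap(i, j);
      v[i] = next_node;
      v.erase(v.begin() + j);
      ++next_node;
      --nactive;
    } else {
      if (!R_finite(t_sched)) {
        stop("stranded lineages: %d lineages left with no coalescence path",
             nactive);
      }
      t = t_sched;
      if (sched_is_event) {
        // apply every event at exactly this time
        while (iev < nev && ev_time[iev] <= t_sched) {
          const int typ = ev_type[iev], p = ev_pop[iev];
          if (typ == 0) {
            ne[p] = ev_ne[iev];
          } else if (typ == 1) {
            const int d = ev_dest[iev];
            if (dead[d]) stop("merge destination population is extinct");
            for (size_t q = 0; q < act[p].size(); ++q)
              act[d].push_back(act[p][q]);
            act[p].clear();
            dead[p] = true;
          } else if (typ == 2) {
            const int d1 = ev_dest[iev], d2 = ev_dest2[iev];
            const double pr = ev_prob[iev];
            for (size_t q = 0; q < act[p].size(); ++q) {
              if (unif_rand() < pr) act[d1].push_back(act[p][q]);
              else act[d2].push_back(act[p][q]);
            }
            act[p].clear();
            dead[p] = true;
          }
          ++iev;
        }
      } else {
        while (iblock < nblock && samp_time[border[iblock]] <= t_sched) {
          const int b = border[iblock];
          if (dead[samp_pop[b]])
            stop("sample scheduled in a population that does not exist then");
          for (int q = 0; q < samp_n[b]; ++q) {
            const int tip = bstart[b] + q;
            ntime[tip] = samp_time[b];
            act[samp_pop[b]].push_back(tip);
          }
          nactive += samp_n[b];
          npending -= samp_n[b];
          ++iblock;
        }
      }
    }
  }

  const int nnode = next_node;
  IntegerVector par(nnode);
  NumericVector tim(nnode);
  for (int i = 0; i < nnode; ++i) { par[i] = parent[i]; tim[i] = ntime[i]; }
  return List::create(_["parent"] = par, _["time"] = tim,
                      _["ntips"] = ntips);
}

// ---------------------------------------------------------------------------
// Microsatellite mutation: generalized stepwise model
// ---------------------------------------------------------------------------

// Poisson(rate * branch length) mutations per branch; each mutation is +-1
// repeat with probability p_gsm, otherwise +-(1 + Geometric(p_geom)) repeats
// (p_geom is the success probability; extra steps have mean (1-p_geom)/p_geom).
// Reflecting boundary at 2 repeats.
// [[Rcpp::export]]
IntegerVector mutate_msat_cpp(IntegerVector parent, NumericVector ntime,
                              int ntips, double rate, double p_gsm,
                              double p_geom, int anc_state) {
  const int nnode = parent.size();
  std::vector<int> state(nnode, anc_state);
  // nodes were created in increasing time order, so iterating from the last
  // internal node down to the tips visits parents before children
  for (int v = nnode - 2; v >= 0; --v) {
    const int pa = parent[v];
    if (pa < 0) { continue; }  // extra root guard
    const double len = ntime[pa] - ntime[v];
    int s = state[pa];
    const int nm = (int)R::rpois(rate * len);
    for (int m = 0; m < nm; ++m) {
      int step = 1;
      if (unif_rand() >= p_gsm) step += (int)R::rgeom(p_geom);
      if (unif_rand() < 0.5) step = -step;
      s += step;
      while (s < 2) s = 4 - s;  // reflect at the 2-repeat floor
    }
    state[v] = s;
  }
  IntegerVector out(ntips);
  for (int i = 0; i < ntips; ++i) out[i] = state[i];
  return out;
}

// ---------------------------------------------------------------------------
// Sequence mutation: HKY by uniformization
// ---------------------------------------------------------------------------

// Exact simulation of the HKY CTMC along each branch via uniformization:
// candidate events arrive at the uniform bound rate; each candidate applies
// one step of the embedded chain (with self-transitions), which reproduces
// the matrix-exponential transition law exactly. States 0..3 = A,C,G,T.
// [[Rcpp::export]]
IntegerMatrix mutate_seq_cpp(IntegerVector parent, NumericVector ntime,
                             int ntips, int L, double rate, double kappa,
                             NumericVector freqs) {
  const int nnode = parent.size();
  double pi[4];
  double s = 0.0;
  for (int i = 0; i < 4; ++i) s += freqs[i];
  for (int i = 0; i < 4; ++i) pi[i] = freqs[i] / s;

  // HKY rate matrix, scaled so the stationary substitution rate is `rate`
  // transitions: A<->G (0,2), C<->T (1,3)
  double Q[4][4];
  for (int i = 0; i < 4; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < 4; ++j) {
      if (i == j) continue;
      const bool ts = (i + j == 2 && i != 1) || (i + j == 4 && i != 0);
      Q[i][j] = (ts ? kappa : 1.0) * pi[j];
      rowsum += Q[i][j];
    }
    Q[i][i] = -rowsum;
  }
  double mean_rate = 0.0;
  for (int i = 0; i < 4; ++i) mean_rate += -Q[i][i] * pi[i];
  if (mean_rate > 0.0) {
    const double f = rate / mean_rate;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) Q[i][j] *= f;
  }
  double rmax = 0.0;
  for (int i = 0; i < 4; ++i) rmax = std::max(rmax, -Q[i][i]);

  std::vector<std::vector<int> > seq(nnode, std::vector<int>(L));
  // root sequence from stationary frequencies
  const int root = nnode - 1;
  for (int l = 0; l < L; ++l) {
    const double u = unif_rand();
    int st = 3;
    double acc = 0.0;
    for (int i = 0; i < 4; ++i) { acc += pi[i]; if (u <= acc) { st = i; break; } }
    seq[root][l] = st;
  }

  for (int v = nnode - 2; v >= 0; --v) {
    const int pa = parent[v];
    seq[v] = seq[pa];
    const double len = ntime[pa] - ntime[v];
    if (rmax <= 0.0 || len <= 0.0) continue;
    const int ncand = (int)R::rpois(rmax * (double)L * len);
    for (int c = 0; c < ncand; ++c) {
      int site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
      const int i = seq[v][site];
      const double u = unif_rand() * rmax;
      // stay with prob 1 - (-Q_ii)/rmax, else move proportional to Q_ij
      double acc = 0.0;
      for (int j = 0; j < 4; ++j) {
        if (j == i) continue;
        acc += Q[i][j];
        if (u <= acc) { seq[v][site] = j; break; }
      }
    }
  }

  IntegerMatrix out(ntips, L);
  for (int i = 0; i < ntips; ++i)
    for (int l = 0; l < L; ++l) out(i, l) = seq[i][l];
  return out;
}

// ---------------------------------------------------------------------------
// Equilibrium heterozygosity conditional on allele count (Cornuet-Luikart)
// ---------------------------------------------------------------------------

// Single-population coalescent of n gene copies in coalescent time units
// (mutations Poisson(theta/2 * branch length)), two-phase mutation
// superimposed, retained only when the simulated sample shows exactly
// k_target alleles. theta is proposed from a grid to keep acceptance
// workable (it is conditioned out by the fixed-k acceptance). Returns the
// unbiased expected heterozygosity of each accepted simulation.
// [[Rcpp::export]]
NumericVector heq_tpm_cpp(int k_target, int n, double p_smm, double p_geom,
                          int iters, NumericVector theta_grid,
                          double max_attempts) {
  const int nnode = 2 * n - 1;
  std::vector<int> parent(nnode), state(nnode);
  std::vector<double> ntime(nnode);
  std::vector<int> active(n);
  NumericVector out(iters);
  const int ng = theta_grid.size();
  // allele counting without per-attempt allocation: offset array + touched list
  const int OFF = 1 << 15;
  std::vector<int> cntarr(2 * OFF, 0);
  std::vector<int> touched;
  touched.reserve(n);

  double attempts = 0.0;
  int got = 0;
  while (got < iters) {
    if (++attempts > max_attempts)
      stop("acceptance rate too low after %.0f attempts; extend the theta "
           "grid", max_attempts);
    const double theta = theta_grid[(int)(unif_rand() * ng) % ng];

    // coalescent tree of n copies
    for (int i = 0; i < n; ++i) { active[i] = i; ntime[i] = 0.0; }
    int nact = n, nxt = n;
    double t = 0.0;
    while (nact > 1) {
      const double k = (double)nact;
      t += exp_rand() / (k * (k - 1.0) / 2.0);
      int i = (int)(unif_rand() * nact); if (i >= nact) i = nact - 1;
      int j = (int)(unif_rand() * (nact - 1)); if (j >= nact - 1) j = nact - 2;
      if (j >= i) ++j;
      parent[active[i]] = nxt; parent[active[j]] = nxt;
      ntime[nxt] = t;
      if (i > j) std::swap(i, j);
      active[i] = nxt;
      active[j] = active[nact - 1];
      --nact; ++nxt;
    }
    parent[nnode - 1] = -1;

    // TPM mutations from the root down
    state[nnode - 1] = 0;
    for (int v = nnode - 2; v >= 0; --v) {
      const double len = ntime[parent[v]] - ntime[v];
      int s = state[parent[v]];
      const int nm = (int)R::rpois(theta / 2.0 * len);
      for (int m = 0; m < nm; ++m) {
        int step = 1;
        if (unif_rand() >= p_smm) step += (int)R::rgeom(p_geom);
        if (unif_rand() < 0.5) step = -step;
        s += step;
      }
      state[v] = s;
    }

    // allele count and unbiased heterozygosity of the sample
    touched.clear();
    int nall = 0;
    bool overflow = false;
    for (int i = 0; i < n; ++i) {
      int s = state[i] + OFF;
      if (s < 0 || s >= 2 * OFF) { overflow = true; break; }
      if (cntarr[s] == 0) { ++nall; touched.push_back(s); }
      cntarr[s]++;
    }
    if (overflow) {
      for (size_t q = 0; q < touched.size(); ++q) cntarr[touched[q]] = 0;
      continue;
    }
    double ss = 0.0;
    for (size_t q = 0; q < touched.size(); ++q) {
      const double p = (double)cntarr[touched[q]] / n;
      ss += p * p;
      cntarr[touched[q]] = 0;
    }
    if (nall != k_target) continue;
    out[got++] = (double)n / (n - 1.0) * (1.0 - ss);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Summary-statistic kernels
// ---------------------------------------------------------------------------

// Weir-Cockerham theta variance components for one locus and two samples,
// accumulated into a[0] (among) and a[1] (among+between+within).
static void wc_accumulate(const std::vector<int> &allelesA,
                          const std::vector<int> &allelesB,
                          double *num, double *den) {
  // alleles are per-gene-copy states; individuals are consecutive pairs
  const int nA = (int)allelesA.size() / 2, nB = (int)allelesB.size() / 2;
  if (nA < 1 || nB < 1) return;
  std::map<int, double> pA, pB, het_ct_A, het_ct_B;
  for (size_t i = 0; i < allelesA.size(); ++i) pA[allelesA[i]] += 1.0;
  for (size_t i = 0; i < allelesB.size(); ++i) pB[allelesB[i]] += 1.0;
  std::map<int, double> all;
  for (std::map<int, double>::iterator it = pA.begin(); it != pA.end(); ++it)
    all[it->first] = 1.0;
  for (std::map<int, double>::iterator it = pB.begin(); it != pB.end(); ++it)
    all[it->first] = 1.0;
  for (int i = 0; i < nA; ++i)
    if (allelesA[2 * i] != allelesA[2 * i + 1]) {
      het_ct_A[allelesA[2 * i]] += 1.0;
      het_ct_A[allelesA[2 * i + 1]] += 1.0;
    }
  for (int i = 0; i < nB; ++i)
    if (allelesB[2 * i] != allelesB[2 * i + 1]) {
      het_ct_B[allelesB[2 * i]] += 1.0;
      het_ct_B[allelesB[2 * i + 1]] += 1.0;
    }

  const double r = 2.0;
  const double nbar = (nA + nB) / 2.0;
  const double nc = (nA + nB - ((double)nA * nA + (double)nB * nB) /
                     (nA + nB)) / (r - 1.0);
  for (std::map<int, double>::iterator it = all.begin(); it != all.end();
       ++it) {
    const int u = it->first;
    const double piA = (pA.count(u) ? pA[u] : 0.0) / (2.0 * nA);
    const double piB = (pB.count(u) ? pB[u] : 0.0) / (2.0 * nB);
    const double pbar = (nA * piA + nB * piB) / (nA + nB);
    const double s2 = (nA * (piA - pbar) * (piA - pbar) +
                       nB * (piB - pbar) * (piB - pbar)) / ((r - 1.0) * nbar);
    const double hA = (het_ct_A.count(u) ? het_ct_A[u] : 0.0) / nA;
    const double hB = (het_ct_B.count(u) ? het_ct_B[u] : 0.0) / nB;
    const double hbar = (nA * hA + nB * hB) / (r * nbar);
    const double a = nbar / nc *
      (s2 - 1.0 / (nbar - 1.0) *
       (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 - hbar / 4.0));
    const double b = nbar / (nbar - 1.0) *
      (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 -
       (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
    const double c = hbar / 2.0;
    *num += a;
    *den += a + b + c;
  }
}

// One-sample and two-sample microsatellite summary statistics.
// geno: individuals x (2*nloc), allele states in repeat units, NA = missing.
// grp: 0-based sample-group index per individual.
// Returns: ones (ngrp x 4: NAL, HET, VAR, MGW), pair (npair x 3: FST, DAS,
// DM2) with pairs ordered (0,1),(0,2),...,(1,2),... and mask matrices.
// [[Rcpp::export]]
List msat_stats_cpp(IntegerMatrix geno, IntegerVector grp, int ngrp,
                    IntegerVector motif) {
  const int nind = geno.nrow();
  const int nloc = geno.ncol() / 2;
  NumericMatrix ones(ngrp, 4);
  std::fill(ones.begin(), ones.end(), 0.0);

  // collect per group x locus allele lists (gene copies, individuals paired)
  std::vector<std::vector<std::vector<int> > > al(
      ngrp, std::vector<std::vector<int> >(nloc));
  for (int i = 0; i < nind; ++i) {
    const int g = grp[i];
    for (int l = 0; l < nloc; ++l) {
      const int a1 = geno(i, 2 * l), a2 = geno(i, 2 * l + 1);
      if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
      al[g][l].push_back(a1);
      al[g][l].push_back(a2);
    }
  }

  for (int g = 0; g < ngrp; ++g) {
    double nal = 0.0, het = 0.0, var = 0.0, mgw = 0.0;
    int nl = 0;
    for (int l = 0; l < nloc; ++l) {
      const std::vector<int> &v = al[g][l];
      const int nc = (int)v.size();
      if (nc < 2) continue;
      ++nl;
      std::map<int, int> cnt;
      double mean = 0.0;
      int mn = v[0], mx = v[0];
      for (int i = 0; i < nc; ++i) {
        cnt[v[i]]++;
        mean += v[i];
        mn = std::min(mn, v[i]);
        mx = std::max(mx, v[i]);
      }
      mean /= nc;
      double ss = 0.0, vv = 0.0;
      for (std::map<int, int>::iterator it = cnt.begin(); it != cnt.end();
           ++it) {
        const double p = (double)it->second / nc;
        ss += p * p;
      }
      for (int i = 0; i < nc; ++i) vv += (v[i] - mean) * (v[i] - mean);
      nal += (double)cnt.size();
      het += (double)nc / (nc - 1.0) * (1.0 - ss);
      var += vv / (nc - 1.0);
      mgw += (double)cnt.size() / ((double)(mx - mn) + 1.0);
    }
    if (nl > 0) {
      ones(g, 0) = nal / nl;
      ones(g, 1) = het / nl;
      ones(g, 2) = var / nl;
      ones(g, 3) = mgw / nl;
    }
  }

  const int npair = ngrp * (ngrp - 1) / 2;
  NumericMatrix pair(npair, 3);
  LogicalMatrix pairmask(npair, 3);
  std::fill(pairmask.begin(), pairmask.end(), false);

  // per-individual indices by group for DAS
  std::vector<std::vector<int> > members(ngrp);
  for (int i = 0; i < nind; ++i) members[grp[i]].push_back(i);

  int pr = 0;
  for (int g1 = 0; g1 < ngrp; ++g1) {
    for (int g2 = g1 + 1; g2 < ngrp; ++g2, ++pr) {
      double num = 0.0, den = 0.0, dm2 = 0.0;
      int nl_dm2 = 0;
      for (int l = 0; l < nloc; ++l) {
        wc_accumulate(al[g1][l], al[g2][l], &num, &den);
        if (al[g1][l].size() >= 2 && al[g2][l].size() >= 2) {
          double m1 = 0.0, m2 = 0.0;
          for (size_t i = 0; i < al[g1][l].size(); ++i) m1 += al[g1][l][i];
          for (size_t i = 0; i < al[g2][l].size(); ++i) m2 += al[g2][l][i];
          m1 /= al[g1][l].size();
          m2 /= al[g2][l].size();
          dm2 += (m1 - m2) * (m1 - m2);
          ++nl_dm2;
        }
      }
      if (den > 0.0) pair(pr, 0) = num / den; else pairmask(pr, 0) = true;
      // shared-allele distance across all between-group individual pairs
      double shared = 0.0;
      int npairs_das = 0;
      for (size_t i = 0; i < members[g1].size(); ++i) {
        for (size_t j = 0; j < members[g2].size(); ++j) {
          const int ii = members[g1][i], jj = members[g2][j];
          double sh = 0.0;
          int nl2 = 0;
          for (int l = 0; l < nloc; ++l) {
            const int a1 = geno(ii, 2 * l), a2 = geno(ii, 2 * l + 1);
            const int b1 = geno(jj, 2 * l), b2 = geno(jj, 2 * l + 1);
            if (a1 == NA_INTEGER || b1 == NA_INTEGER) continue;
            ++nl2;
            // proportion of shared alleles (0, .5, 1) for this locus
            int s12 = 0;
            int ua[2] = {a1, a2}, ub[2] = {b1, b2};
            bool used[2] = {false, false};
            for (int x = 0; x < 2; ++x)
              for (int y = 0; y < 2; ++y)
                if (!used[y] && ua[x] == ub[y]) { used[y] = true; ++s12; break; }
            sh += s12 / 2.0;
          }
          if (nl2 > 0) { shared += sh / nl2; ++npairs_das; }
        }
      }
      if (npairs_das > 0) pair(pr, 1) = 1.0 - shared / npairs_das;
      else pairmask(pr, 1) = true;
      if (nl_dm2 > 0) pair(pr, 2) = dm2 / nl_dm2; else pairmask(pr, 2) = true;
    }
  }
  return List::create(_["ones"] = ones, _["pair"] = pair,
                      _["pairmask"] = pairmask);
}

// Sequence summary statistics on complete (gap/N-free) integer alignments.
// seqs: individuals x L, states 0..3. grp: 0-based group per sequence.
// Per group: NHA (haplotype count), NSS (segregating sites), MPD (mean
// pairwise differences), DTA (Tajima's D; masked when undefined).
// Per pair: FSH (Hudson Fst from within/between mean differences; masked
// when between-diversity is 0), MPB (mean between-group differences).
// [[Rcpp::export]]
List seq_stats_cpp(IntegerMatrix seqs, IntegerVector grp, int ngrp) {
  const int n = seqs.nrow(), L = seqs.ncol();

  // collapse to haplotypes
  std::unordered_map<std::string, int> hmap;
  std::vector<int> hap(n);
  std::vector<std::vector<int> > hapseq;
  for (int i = 0; i < n; ++i) {
    std::string key((const char *)0, 0);
    key.reserve(L);
    for (int l = 0; l < L; ++l) key.push_back((char)('A' + seqs(i, l)));
    std::unordered_map<std::string, int>::iterator it = hmap.find(key);
    if (it == hmap.end()) {
      const int id = (int)hapseq.size();
      hmap[key] = id;
      hap[i] = id;
      std::vector<int> s(L);
      for (int l = 0; l < L; ++l) s[l] = seqs(i, l);
      hapseq.push_back(s);
    } else hap[i] = it->second;
  }
  const int nh = (int)hapseq.size();
  NumericMatrix hd(nh, nh);
  for (int a = 0; a < nh; ++a)
    for (int b = a + 1; b < nh; ++b) {
      int d = 0;
      for (int l = 0; l < L; ++l) if (hapseq[a][l] != hapseq[b][l]) ++d;
      hd(a, b) = hd(b, a) = (double)d;
    }

  std::vector<std::vector<int> > members(ngrp);
  for (int i = 0; i < n; ++i) members[grp[i]].push_back(i);

  NumericMatrix ones(ngrp, 4);
  LogicalMatrix onesmask(ngrp, 4);
  std::fill(onesmask.begin(), onesmask.end(), false);

  std::vector<double> within(ngrp, 0.0);
  for (int g = 0; g < ngrp; ++g) {
    const std::vector<int> &mem = members[g];
    const int m = (int)mem.size();
    if (m < 2) {
      onesmask(g, 0) = onesmask(g, 1) = onesmask(g, 2) = onesmask(g, 3) = true;
      ones(g, 0) = (m == 1) ? 1.0 : 0.0;
      onesmask(g, 0) = (m == 0);
      continue;
    }
    std::map<int, int> hc;
    for (int i = 0; i < m; ++i) hc[hap[mem[i]]]++;
    ones(g, 0) = (double)hc.size();
    // segregating sites within the group
    int S = 0;
    for (int l = 0; l < L; ++l) {
      const int first = seqs(mem[0], l);
      for (int i = 1; i < m; ++i)
        if (seqs(mem[i], l) != first) { ++S; break; }
    }
    ones(g, 1) = (double)S;
    double mpd = 0.0;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) mpd += hd(hap[mem[i]], hap[mem[j]]);
    mpd /= (double)m * (m - 1.0) / 2.0;
    ones(g, 2) = mpd;
    within[g] = mpd;
    // Tajima's D
    if (S == 0 || m < 4) {
      onesmask(g, 3) = true;
    } else {
      double a1 = 0.0, a2 = 0.0;
      for (int i = 1; i < m; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
      const double b1 = (m + 1.0) / (3.0 * (m - 1.0));
      const double b2 = 2.0 * (m * m + m + 3.0) / (9.0 * m * (m - 1.0));
      const double c1 = b1 - 1.0 / a1;
      const double c2 = b2 - (m + 2.0) / (a1 * m) + a2 / (a1 * a1);
      const double e1 = c1 / a1;
      const double e2 = c2 / (a1 * a1 + a2);
      const double sd = std::sqrt(e1 * S + e2 * S * (S - 1.0));
      if (sd > 0.0) ones(g, 3) = (mpd - S / a1) / sd;
      else onesmask(g, 3) = true;
    }
  }

  const int npair = ngrp * (ngrp - 1) / 2;
  NumericMatrix pair(npair, 2);
  LogicalMatrix pairmask(npair, 2);
  std::fill(pairmask.begin(), pairmask.end(), false);
  int pr = 0;
  for (int g1 = 0; g1 < ngrp; ++g1)
    for (int g2 = g1 + 1; g2 < ngrp; ++g2, ++pr) {
      const std::vector<int> &m1 = members[g1], &m2 = members[g2];
      if (m1.empty() || m2.empty()) {
        pairmask(pr, 0) = pairmask(pr, 1) = true;
        continue;
      }
      double between = 0.0;
      for (size_t i = 0; i < m1.size(); ++i)
        for (size_t j = 0; j < m2.size(); ++j)
          between += hd(hap[m1[i]], hap[m2[j]]);
      between /= (double)m1.size() * (double)m2.size();
      pair(pr, 1) = between;
      if (between > 0.0 && m1.size() >= 2 && m2.size() >= 2) {
        const double hw = (within[g1] + within[g2]) / 2.0;
        pair(pr, 0) = 1.0 - hw / between;
      } else pairmask(pr, 0) = true;
    }

  return List::create(_["ones"] = ones, _["onesmask"] = onesmask,
                      _["pair"] = pair, _["pairmask"] = pairmask);
}
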