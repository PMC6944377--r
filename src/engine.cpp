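// Core simulation engine: crossover sampling under the Poisson and
// Housworth-Stahl two-pathway interference models, meiosis on
// founder-segment haplotypes, pedigree transmission over replicates, and
// exact IBD extraction for designated pairs.
//
// All randomness comes from R's RNG so results are reproducible from
// set.seed().  Draw order within a meiosis is fixed: free (escape-pathway)
// events first, then regulated chiasmata, then the thinning coins.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------- crossover sampling (genetic axis, Morgans) ----------

static void sample_xo_poisson(double L, std::vector<double> &out) {
  out.clear();
  double x = R::exp_rand();
  while (x < L) {
    out.push_back(x);
    x += R::exp_rand();
  }
}

// Stationary two-pathway sample on [0, L]: the regulated gamma renewal is
// started from a burn-in offset B before coordinate 0 so that the process
// observed on [0, L] is (to numerical accuracy) stationary.
static void sample_xo_stahl(double L, double nu, double p,
                            std::vector<double> &out,
                            std::vector<double> &scratch) {
  out.clear();
  if (p > 0) { // free pathway: Poisson, rate p per Morgan
    double x = R::exp_rand() / p;
    while (x < L) {
      out.push_back(x);
      x += R::exp_rand() / p;
    }
  }
  if (p < 1) { // regulated pathway: gamma(nu, 2*nu*(1-p)) chiasma renewal
    double rate = 2.0 * nu * (1.0 - p);
    double scale = 1.0 / rate;
    double B = std::max(10.0, 5.0 / rate);
    scratch.clear();
    double pos = -B;
    for (;;) {
      pos += R::rgamma(nu, scale);
      if (pos >= L)
        break;
      if (pos > 0)
        scratch.push_back(pos);
    }
    for (size_t i = 0; i < scratch.size(); ++i) // thinning, no chromatid interference
      if (unif_rand() < 0.5)
        out.push_back(scratch[i]);
  }
  std::sort(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericVector cpp_sample_crossovers(double L, bool interference, double nu,
                                    double p) {
  std::vector<double> out, scratch;
  if (interference && p < 1)
    sample_xo_stahl(L, nu, p, out, scratch);
  else
    sample_xo_poisson(L, out);
  return NumericVector(out.begin(), out.end());
}

// ---------- genetic map ----------

struct ChromMap {
  std::vector<double> pos;      // bp (knots)
  std::vector<double> gm, gf;   // cumulative Morgans, male / female axis
  std::vector<double> ga;       // cumulative sex-averaged cM (output axis)
  double Lm, Lf;                // genetic lengths, Morgans
};

static std::vector<ChromMap> build_maps(const List &chrom_maps) {
  std::vector<ChromMap> maps(chrom_maps.size());
  for (int c = 0; c < chrom_maps.size(); ++c) {
    List m = chrom_maps[c];
    NumericVector pos = m["pos"], male = m["male"], female = m["female"];
    ChromMap &cm = maps[c];
    int n = pos.size();
    cm.pos.assign(pos.begin(), pos.end());
    cm.gm.resize(n);
    cm.gf.resize(n);
    cm.ga.resize(n);
    for (int i = 0; i < n; ++i) {
      cm.gm[i] = (male[i] - male[0]) / 100.0;
      cm.gf[i] = (female[i] - female[0]) / 100.0;
      cm.ga[i] = (male[i] + female[i]) / 2.0;
    }
    cm.Lm = cm.gm[n - 1];
    cm.Lf = cm.gf[n - 1];
  }
  return maps;
}

// genetic (Morgans, given axis) -> physical bp (real-valued)
static double gen2phys(const std::vector<double> &g,
                       const std::vector<double> &pos, double u) {
  size_t i = std::upper_bound(g.begin(), g.end(), u) - g.begin();
  if (i >= g.size())
    return pos.back();
  if (i == 0)
    return pos.front();
  size_t lo = i - 1;
  double den = g[i] - g[lo];
  if (den <= 0)
    return pos[lo];
  return pos[lo] + (u - g[lo]) / den * (pos[i] - pos[lo]);
}

// physical bp -> sex-averaged cM
static double phys2avg(const ChromMap &cm, double x) {
  const std::vector<double> &pos = cm.pos;
  size_t i = std::upper_bound(pos.begin(), pos.end(), x) - pos.begin();
  if (i >= pos.size())
    return cm.ga.back();
  if (i == 0)
    return cm.ga.front();
  size_t lo = i - 1;
  double den = pos[i] - pos[lo];
  return cm.ga[lo] + (x - pos[lo]) / den * (cm.ga[i] - cm.ga[lo]);
}

// ---------- haplotypes and meiosis ----------

struct Hap {
  std::vector<double> ends; // bp, strictly increasing; last = chrom end
  std::vector<int> ids;     // founder haplotype ids (1-based)
};

static inline void push_run(Hap &g, double e, int id) {
  if (!g.ends.empty()) {
    if (e <= g.ends.back())
      return; // zero-length run
    if (g.ids.back() == id) {
      g.ends.back() = e;
      return;
    }
  }
  g.ends.push_back(e);
  g.ids.push_back(id);
}

// Transmit one gamete from a parent's two haplotypes given crossover
// breakpoints (bp, strictly processed in order).  `start` selects the
// haplotype that begins the gamete.
static void make_gamete(const Hap &h0, const Hap &h1,
                        const std::vector<double> &brk, int start,
                        double chrom_end, Hap &out) {
  out.ends.clear();
  out.ids.clear();
  const Hap *src[2] = {&h0, &h1};
  size_t idx[2] = {0, 0};
  int cur = start;
  double prev = -1.0;
  for (size_t b = 0; b <= brk.size(); ++b) {
    double stop = (b < brk.size()) ? brk[b] : chrom_end;
    const Hap &s = *src[cur];
    size_t &j = idx[cur];
    while (j < s.ends.size() && s.ends[j] < stop) {
      if (s.ends[j] > prev)
        push_run(out, s.ends[j], s.ids[j]);
      ++j;
    }
    if (j < s.ends.size() && stop > prev)
      push_run(out, stop, s.ids[j]);
    prev = std::max(prev, stop);
    cur = 1 - cur;
  }
}

// Meiosis for one chromosome: sample crossovers on the parent-sex genetic
// axis, map them to bp (floored to integers), and recombine.
static void meiosis(const Hap &h0, const Hap &h1, const ChromMap &cm,
                    int parent_sex /*1=male,2=female*/, bool intf, double nu,
                    double p, std::vector<double> &xo,
                    std::vector<double> &scratch, std::vector<double> &brk,
                    Hap &out) {
  double L = (parent_sex == 1) ? cm.Lm : cm.Lf;
  const std::vector<double> &g = (parent_sex == 1) ? cm.gm : cm.gf;
  if (intf && p < 1)
    sample_xo_stahl(L, nu, p, xo, scratch);
  else
    sample_xo_poisson(L, xo);
  brk.clear();
  for (size_t i = 0; i < xo.size(); ++i)
    brk.push_back(std::floor(gen2phys(g, cm.pos, xo[i])));
  int start = (unif_rand() < 0.5) ? 0 : 1;
  make_gamete(h0, h1, brk, start, cm.pos.back(), out);
}

// ---------- IBD sweep for a pair ----------

// Maximal matching between {a1,a2} and {b1,b2}: 2 -> IBD2, 1 -> IBD1.
static inline int match_count(int a1, int a2, int b1, int b2) {
  int m1 = (a1 == b1) + (a2 == b2);
  int m2 = (a1 == b2) + (a2 == b1);
  return m1 > m2 ? m1 : m2;
}

struct IBDOut {
  std::vector<int> rep, id1, id2, chrom, type;
  std::vector<double> start, end, gstart, gend;
};

static void ibd_pair_chrom(const Hap *A[2], const Hap *B[2],
                           const ChromMap &cm, int rep, int i1, int i2,
                           int chrom, IBDOut &out) {
  // merged breakpoints of the four haplotypes
  std::vector<double> E;
  for (int h = 0; h < 2; ++h) {
    E.insert(E.end(), A[h]->ends.begin(), A[h]->ends.end());
    E.insert(E.end(), B[h]->ends.begin(), B[h]->ends.end());
  }
  std::sort(E.begin(), E.end());
  E.erase(std::unique(E.begin(), E.end()), E.end());
  size_t ja1 = 0, ja2 = 0, jb1 = 0, jb2 = 0;
  double seg_start = cm.pos.front();
  double prev = cm.pos.front() - 1.0;
  int cur_type = 0;
  double cur_start = 0;
  for (size_t k = 0; k < E.size(); ++k) {
    double e = E[k];
    while (A[0]->ends[ja1] < e)
      ++ja1;
    while (A[1]->ends[ja2] < e)
      ++ja2;
    while (B[0]->ends[jb1] < e)
      ++jb1;
    while (B[1]->ends[jb2] < e)
      ++jb2;
    int t = match_count(A[0]->ids[ja1], A[1]->ids[ja2], B[0]->ids[jb1],
                        B[1]->ids[jb2]);
    seg_start = prev + 1.0;
    if (t != cur_type) {
      if (cur_type > 0) {
        out.rep.push_back(rep);
        out.id1.push_back(i1);
        out.id2.push_back(i2);
        out.chrom.push_back(chrom);
        out.type.push_back(cur_type);
        out.start.push_back(cur_start);
        out.end.push_back(prev);
        out.gstart.push_back(phys2avg(cm, cur_start));
        out.gend.push_back(phys2avg(cm, prev));
      }
      cur_type = t;
      cur_start = seg_start;
    }
    prev = e;
  }
  if (cur_type > 0) {
    out.rep.push_back(rep);
    out.id1.push_back(i1);
    out.id2.push_back(i2);
    out.chrom.push_back(chrom);
    out.type.push_back(cur_type);
    out.start.push_back(cur_start);
    out.end.push_back(prev);
    out.gstart.push_back(phys2avg(cm, cur_start));
    out.gend.push_back(phys2avg(cm, prev));
  }
}

// ---------- pedigree engine ----------

// parent1/parent2: 0-based indices, -1 for founders; individuals must be in
// topological order (parents precede children).  sex_fixed: 0 = free,
// 1 = male, 2 = female.  couples: rows of co-parent index pairs in the
// order sex assignment should resolve them.  nu_f/p_f/nu_m/p_m: one value
// per chromosome.  pairs: rows of individual index pairs for IBD output.
// [[Rcpp::export]]
List cpp_sim_pedigree(List chrom_maps, IntegerVector parent1,
                      IntegerVector parent2, IntegerVector sex_fixed,
                      IntegerMatrix couples, bool interference,
                      NumericVector nu_f, NumericVector p_f,
                      NumericVector nu_m, NumericVector p_m,
                      IntegerVector print_idx, IntegerMatrix pairs, int n_reps,
                      bool return_ibd, bool return_haps) {
  std::vector<ChromMap> maps = build_maps(chrom_maps);
  int n_chrom = maps.size();
  int n_ind = parent1.size();

  // founder numbering in individual order
  std::vector<int> founder_base(n_ind, -1);
  int n_founders = 0;
  for (int i = 0; i < n_ind; ++i)
    if (parent1[i] < 0)
      founder_base[i] = 2 * (n_founders++);

  // haplotype storage: [ind][hap][chrom]
  std::vector<std::vector<std::vector<Hap>>> hap(
      n_ind, std::vector<std::vector<Hap>>(2, std::vector<Hap>(n_chrom)));
  std::vector<int> sex(n_ind);
  IntegerMatrix sexes_out(n_reps, n_ind);

  IBDOut ibd;
  // flat haplotype output
  std::vector<int> ho_rep, ho_ind, ho_hap, ho_chrom, ho_id;
  std::vector<double> ho_end;

  std::vector<double> xo, scratch, brk;

  for (int rep = 0; rep < n_reps; ++rep) {
    // --- sexes ---
    for (int i = 0; i < n_ind; ++i)
      sex[i] = sex_fixed[i];
    for (int r = 0; r < couples.nrow(); ++r) {
      int a = couples(r, 0), b = couples(r, 1);
      if (sex[a] != 0)
        sex[b] = 3 - sex[a];
      else if (sex[b] != 0)
        sex[a] = 3 - sex[b];
      else {
        sex[a] = (unif_rand() < 0.5) ? 1 : 2;
        sex[b] = 3 - sex[a];
      }
    }
    for (int i = 0; i < n_ind; ++i) {
      if (sex[i] == 0)
        sex[i] = (unif_rand() < 0.5) ? 1 : 2; // non-reproducing individuals
      sexes_out(rep, i) = sex[i];
    }

    // --- transmission ---
    for (int i = 0; i < n_ind; ++i) {
      if (parent1[i] < 0) { // founder: one chromosome-length run per haplotype
        for (int c = 0; c < n_chrom; ++c)
          for (int h = 0; h < 2; ++h) {
            Hap &hp = hap[i][h][c];
            hp.ends.assign(1, maps[c].pos.back());
            hp.ids.assign(1, founder_base[i] + h + 1);
          }
      } else {
        int par[2] = {parent1[i], parent2[i]};
        for (int h = 0; h < 2; ++h) {
          int ps = sex[par[h]];
          for (int c = 0; c < n_chrom; ++c) {
            double nu = (ps == 1) ? nu_m[c] : nu_f[c];
            double p = (ps == 1) ? p_m[c] : p_f[c];
            meiosis(hap[par[h]][0][c], hap[par[h]][1][c], maps[c], ps,
                    interference, nu, p, xo, scratch, brk, hap[i][h][c]);
          }
        }
      }
    }

    // --- outputs ---
    if (return_ibd) {
      for (int r = 0; r < pairs.nrow(); ++r) {
        int i1 = pairs(r, 0), i2 = pairs(r, 1);
        for (int c = 0; c < n_chrom; ++c) {
          const Hap *A[2] = {&hap[i1][0][c], &hap[i1][1][c]};
          const Hap *B[2] = {&hap[i2][0][c], &hap[i2][1][c]};
          ibd_pair_chrom(A, B, maps[c], rep + 1, i1 + 1, i2 + 1, c + 1, ibd);
        }
      }
    }
    if (return_haps) {
      for (int k = 0; k < print_idx.size(); ++k) {
        int i = print_idx[k];
        for (int h = 0; h < 2; ++h)
          for (int c = 0; c < n_chrom; ++c) {
            const Hap &hp = hap[i][h][c];
            for (size_t s = 0; s < hp.ends.size(); ++s) {
              ho_rep.push_back(rep + 1);
              ho_ind.push_back(i + 1);
              ho_hap.push_back(h + 1);
              ho_chrom.push_back(c + 1);
              ho_end.push_back(hp.ends[s]);
              ho_id.push_back(hp.ids[s]);
            }
          }
      }
    }
  }

  List out;
  out["sexes"] = sexes_out;
  if (return_ibd) {
    out["ibd"] = DataFrame::create(
        _["rep"] = ibd.rep, _["id1"] = ibd.id1, _["id2"] = ibd.id2,
        _["chrom"] = ibd.chrom, _["start_bp"] = ibd.start,
        _["end_bp"] = ibd.end, _["type"] = ibd.type,
        _["gen_start"] = ibd.gstart, _["gen_end"] = ibd.gend);
  }
  if (return_haps) {
    out["haps"] = DataFrame::create(
        _["rep"] = ho_rep, _["ind"] = ho_ind, _["hap"] = ho_hap,
        _["chrom"] = ho_chrom, _["end_bp"] = ho_end, _["founder_id"] = ho_id);
  }
  return out;
}
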