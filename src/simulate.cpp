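// Forward-time simulator core: sex-structured admixture with Poisson
// recombination (Haldane) on a cM map, fully sex-linked X, patrilineal Y
// and matrilineal mtDNA labels. Discrete non-overlapping generations,
// constant pool size. All randomness comes from R's RNG so set.seed()
// makes runs reproducible.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// A haplotype is a set of ancestry tracts tiling [0, L): tract i spans
// [start[i], start[i+1]) (last tract ends at L) and carries label lab[i].
struct Hap {
  std::vector<double> start;
  std::vector<int> lab;
};

struct Indiv {
  bool female;
  std::vector<Hap> aut;   // 2 per autosome: [2*c], [2*c+1]
  Hap x0, x1;             // females: both used; males: x0 only
  int mt, y;              // source labels (y = -1 for females)
  int mother_mt, father_y; // parental uniparental labels (for checks)
};

// Append tracts of h clipped to [a, b) onto child, merging equal labels.
void copy_interval(const Hap& h, double a, double b, Hap& child) {
  if (b <= a) return;
  size_t i = 0;
  // last tract with start <= a
  while (i + 1 < h.start.size() && h.start[i + 1] <= a) ++i;
  for (; i < h.start.size(); ++i) {
    double s = std::max(h.start[i], a);
    double e = (i + 1 < h.start.size()) ? std::min(h.start[i + 1], b) : b;
    if (s >= b) break;
    if (e <= s) continue;
    if (!child.lab.empty() && child.lab.back() == h.lab[i]) continue; // merge
    child.start.push_back(s);
    child.lab.push_back(h.lab[i]);
  }
}

// One meiosis: recombine the two parental haplotypes over [0, L).
Hap meiosis(const Hap& h0, const Hap& h1, double L) {
  int ncross = (int) R::rpois(L / 100.0);
  int phase = (unif_rand() < 0.5) ? 0 : 1;
  if (ncross == 0) return phase == 0 ? h0 : h1;
  std::vector<double> cx(ncross);
  for (int i = 0; i < ncross; ++i) cx[i] = unif_rand() * L;
  std::sort(cx.begin(), cx.end());
  cx.push_back(L);
  Hap child;
  double a = 0.0;
  for (size_t i = 0; i < cx.size(); ++i) {
    const Hap& src = (phase == 0) ? h0 : h1;
    copy_interval(src, a, cx[i], child);
    a = cx[i];
    phase = 1 - phase;
  }
  return child;
}

Hap single_tract(int k) {
  Hap h;
  h.start.push_back(0.0);
  h.lab.push_back(k);
  return h;
}

// Fresh unadmixed migrant from source k.
Indiv migrant(int k, bool female, int n_aut) {
  Indiv ind;
  ind.female = female;
  ind.aut.resize(2 * n_aut);
  for (int c = 0; c < n_aut; ++c) {
    ind.aut[2 * c] = single_tract(k);
    ind.aut[2 * c + 1] = single_tract(k);
  }
  ind.x0 = single_tract(k);
  if (female) ind.x1 = single_tract(k);
  ind.mt = k;
  ind.y = female ? -1 : k;
  ind.mother_mt = k;
  ind.father_y = k;
  return ind;
}

// Draw a source index from row g of a (G+1) x K fraction matrix, or -1
// if the draw falls in the "existing pool" remainder.
int draw_source(const NumericMatrix& s, int g, double u) {
  double acc = 0.0;
  for (int k = 0; k < s.ncol(); ++k) {
    acc += s(g, k);
    if (u < acc) return k;
  }
  return -1;
}

void accum_fractions(const Hap& h, double L, std::vector<double>& out) {
  for (size_t i = 0; i < h.start.size(); ++i) {
    double e = (i + 1 < h.start.size()) ? h.start[i + 1] : L;
    out[h.lab[i]] += e - h.start[i];
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_admixture_core")]]
List sim_admixture_core(NumericVector aut_len, double x_len,
                        NumericMatrix sf, NumericMatrix sm,
                        int pool_size, int n_out) {
  const int n_aut = aut_len.size();
  const int K = sf.ncol();
  const int G = sf.nrow() - 1; // rows 0..G; row 0 founds the population
  const bool has_x = R_finite(x_len) && x_len > 0;

  std::vector<Indiv> pool(pool_size), next(pool_size);

  // Generation 0: every individual is a fresh single-source founder.
  for (int i = 0; i < pool_size; ++i) {
    bool female = unif_rand() < 0.5;
    int k = draw_source(female ? sf : sm, 0, unif_rand());
    if (k < 0) k = K - 1; // guard against rounding; row 0 sums to 1
    pool[i] = migrant(k, female, n_aut);
  }

  std::vector<int> fem_idx, mal_idx;
  for (int g = 1; g <= G; ++g) {
    fem_idx.clear(); mal_idx.clear();
    for (int i = 0; i < pool_size; ++i)
      (pool[i].female ? fem_idx : mal_idx).push_back(i);
    if (fem_idx.empty() || mal_idx.empty())
      stop("mating pool lost one sex entirely; increase pool_size");

    for (int i = 0; i < pool_size; ++i) {
      bool female = unif_rand() < 0.5;
      int mk = draw_source(sf, g, unif_rand());
      int pk = draw_source(sm, g, unif_rand());
      Indiv mtmp, ptmp;
      const Indiv* mo;
      const Indiv* fa;
      if (mk >= 0) { mtmp = migrant(mk, true, n_aut); mo = &mtmp; }
      else mo = &pool[fem_idx[(int)(unif_rand() * fem_idx.size())]];
      if (pk >= 0) { ptmp = migrant(pk, false, n_aut); fa = &ptmp; }
      else fa = &pool[mal_idx[(int)(unif_rand() * mal_idx.size())]];

      Indiv ch;
      ch.female = female;
      ch.aut.resize(2 * n_aut);
      for (int c = 0; c < n_aut; ++c) {
        ch.aut[2 * c]     = meiosis(mo->aut[2 * c], mo->aut[2 * c + 1], aut_len[c]);
        ch.aut[2 * c + 1] = meiosis(fa->aut[2 * c], fa->aut[2 * c + 1], aut_len[c]);
      }
      if (has_x) {
        // mother's X recombines; father passes his X intact to daughters
        ch.x0 = mo->female ? meiosis(mo->x0, mo->x1, x_len) : mo->x0;
        if (!mo->female) stop("internal: mother not female");
        if (female) ch.x1 = fa->x0;
      }
      ch.mt = mo->mt;
      ch.mother_mt = mo->mt;
      ch.y = female ? -1 : fa->y;
      ch.father_y = fa->y;
      next[i] = ch;
    }
    std::swap(pool, next);
  }

  // Sample n_out individuals without replacement (partial Fisher-Yates).
  std::vector<int> perm(pool_size);
  for (int i = 0; i < pool_size; ++i) perm[i] = i;
  for (int i = 0; i < n_out; ++i) {
    int j = i + (int)(unif_rand() * (pool_size - i));
    std::swap(perm[i], perm[j]);
  }

  // Flatten tracts to long format and compute true fractions.
  std::vector<int> t_ind, t_hap, t_chr, t_lab; // chr: 1..n_aut, 0 = X
  std::vector<double> t_start, t_end;
  IntegerVector sex(n_out), mt(n_out), y(n_out), mo_mt(n_out), fa_y(n_out);
  NumericMatrix frac_aut(n_out, K), frac_x(n_out, K);
  double tot_aut = 0.0;
  for (int c = 0; c < n_aut; ++c) tot_aut += aut_len[c];

  for (int i = 0; i < n_out; ++i) {
    const Indiv& ind = pool[perm[i]];
    sex[i] = ind.female ? 1 : 2;
    mt[i] = ind.mt + 1;
    y[i] = ind.female ? NA_INTEGER : ind.y + 1;
    mo_mt[i] = ind.mother_mt + 1;
    fa_y[i] = ind.father_y + 1;

    std::vector<double> fa_acc(K, 0.0), fx_acc(K, 0.0);
    for (int c = 0; c < n_aut; ++c)
      for (int hap = 0; hap < 2; ++hap) {
        const Hap& h = ind.aut[2 * c + hap];
        accum_fractions(h, aut_len[c], fa_acc);
        for (size_t t = 0; t < h.start.size(); ++t) {
          t_ind.push_back(i + 1); t_hap.push_back(hap + 1);
          t_chr.push_back(c + 1); t_lab.push_back(h.lab[t] + 1);
          t_start.push_back(h.start[t]);
          t_end.push_back(t + 1 < h.start.size() ? h.start[t + 1] : aut_len[c]);
        }
      }
    double x_tot = 0.0;
    if (has_x) {
      int nx = ind.female ? 2 : 1;
      for (int hap = 0; hap < nx; ++hap) {
        const Hap& h = (hap == 0) ? ind.x0 : ind.x1;
        accum_fractions(h, x_len, fx_acc);
        for (size_t t = 0; t < h.start.size(); ++t) {
          t_ind.push_back(i + 1); t_hap.push_back(hap + 1);
          t_chr.push_back(0); t_lab.push_back(h.lab[t] + 1);
          t_start.push_back(h.start[t]);
          t_end.push_back(t + 1 < h.start.size() ? h.start[t + 1] : x_len);
        }
      }
      x_tot = nx * x_len;
    }
    for (int k = 0; k < K; ++k) {
      frac_aut(i, k) = fa_acc[k] / (2.0 * tot_aut);
      if (has_x) frac_x(i, k) = fx_acc[k] / x_tot;
    }
  }

  return List::create(
    _["sex"] = sex, _["mt"] = mt, _["y"] = y,
    _["mother_mt"] = mo_mt, _["father_y"] = fa_y,
    _["frac_aut"] = frac_aut, _["frac_x"] = frac_x,
    _["tract_ind"] = wrap(t_ind), _["tract_hap"] = wrap(t_hap),
    _["tract_chr"] = wrap(t_chr), _["tract_lab"] = wrap(t_lab),
    _["tract_start"] = wrap(t_start), _["tract_end"] = wrap(t_end));
}

// Joint counts of ordered ancestry label pairs at grid lags.
// lab: integer labels in 1..K along a regular grid on one haplotype;
// returns K x K x max_lag array of pair counts.
// [[Rcpp::export(name = ".lag_pair_counts")]]
IntegerVector lag_pair_counts(IntegerVector lab, int K, int max_lag) {
  int n = lab.size();
  IntegerVector out(K * K * max_lag);
  const int* p = INTEGER(lab);
  int* o = INTEGER(out);
  for (int l = 1; l <= max_lag; ++l) {
    int* base = o + (size_t)(l - 1) * K * K;
    for (int i = 0; i + l < n; ++i) {
      int a = p[i], b = p[i + l];
      if (a == NA_INTEGER || b == NA_INTEGER) continue;
      ++base[(a - 1) + K * (b - 1)];
    }
  }
  out.attr("dim") = IntegerVector::create(K, K, max_lag);
  return out;
}
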