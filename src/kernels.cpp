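// Compiled kernels for the pattern-similarity pipeline: cross-mini-block
// correlation averaging, the volumetric searchlight, TFCE, and the
// sign-flip group map test. All randomness goes through R's RNG so results
// are reproducible from set.seed().

#include <RcppArmadillo.h>
#include <functional>
#include <array>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double CLIP = 1.0 - 1e-7;

static inline double fisher_z(double r) {
  if (r > CLIP) r = CLIP;
  if (r < -CLIP) r = -CLIP;
  return 0.5 * std::log((1.0 + r) / (1.0 - r));
}

// Standardize rows of X to zero mean / unit norm so Z * Z.t() is the row
// correlation matrix.
static arma::mat row_standardize(const arma::mat& X) {
  arma::mat Z = X;
  const arma::uword V = Z.n_cols;
  for (arma::uword i = 0; i < Z.n_rows; ++i) {
    double mu = arma::mean(Z.row(i));
    Z.row(i) -= mu;
    double nrm = arma::norm(Z.row(i), 2);
    if (nrm > 0) Z.row(i) /= nrm;
  }
  (void)V;
  return Z;
}

// Mean Fisher-z cross-block similarity per unordered event pair.
// X: (n_events * m) x V, row (e * m + b). Pair order matches combn(n, 2).
static arma::vec mean_z_pairs(const arma::mat& X, int n_events, int m) {
  arma::mat Z = row_standardize(X);
  arma::mat C = Z * Z.t();
  int n_pairs = n_events * (n_events - 1) / 2;
  arma::vec out(n_pairs);
  int p = 0;
  for (int i = 0; i < n_events - 1; ++i) {
    for (int j = i + 1; j < n_events; ++j) {
      double acc = 0.0;
      int cnt = 0;
      const int ri0 = i * m, rj0 = j * m;
      for (int a = 0; a < m; ++a) {
        for (int b = 0; b < m; ++b) {
          if (a == b) continue;
          acc += fisher_z(C(ri0 + a, rj0 + b));
          ++cnt;
        }
      }
      out(p++) = acc / cnt;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_cross_block_mean_z(const arma::mat& X, int n_events, int m) {
  return mean_z_pairs(X, n_events, m);
}

// OLS focal t-statistic with precomputed projector pieces.
struct OlsModel {
  arma::mat X;        // n x p (includes intercept)
  arma::mat A;        // p x n  = (X'X)^-1 X'
  arma::vec invdiag;  // diag((X'X)^-1)
  arma::uvec rows;    // 0-based indices into the pair vector
  int focal;          // 0-based coefficient index
};

static OlsModel make_model(const arma::mat& X, const arma::uvec& rows, int focal) {
  OlsModel mdl;
  mdl.X = X;
  arma::mat XtXi = arma::inv_sympd(X.t() * X);
  mdl.A = XtXi * X.t();
  mdl.invdiag = XtXi.diag();
  mdl.rows = rows;
  mdl.focal = focal;
  return mdl;
}

static double focal_t(const OlsModel& mdl, const arma::vec& y_all) {
  arma::vec y = y_all.elem(mdl.rows);
  arma::vec coef = mdl.A * y;
  double rss = arma::dot(y, y) - arma::dot(coef, mdl.X.t() * y);
  int n = mdl.X.n_rows, p = mdl.X.n_cols;
  double s2 = rss / (n - p);
  double se = std::sqrt(s2 * mdl.invdiag(mdl.focal));
  if (se <= 0) return NA_REAL;
  return coef(mdl.focal) / se;
}

// Searchlight over a volume. pre/post: (n_events * m) x V_brain pattern
// matrices; coords: V_brain x 3 (1-based voxel indices); gray: gray-matter
// flag per brain voxel. models: list of list(X, rows (1-based), focal
// (1-based)). Spheres with <= min_gray gray voxels are skipped (NaN).
// [[Rcpp::export]]
arma::mat cpp_searchlight(const arma::mat& pre, const arma::mat& post,
                          const arma::imat& coords, const LogicalVector& gray,
                          const IntegerVector& dims, int n_events, int m,
                          double radius, int min_gray, const List& models) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = coords.n_rows;

  // voxel (x,y,z) -> brain column lookup
  std::vector<int> lut((size_t)nx * ny * nz, -1);
  for (int v = 0; v < V; ++v) {
    int x = coords(v, 0) - 1, y = coords(v, 1) - 1, z = coords(v, 2) - 1;
    lut[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = v;
  }

  // integer sphere offsets, ||.|| <= radius (voxel units)
  std::vector<std::array<int, 3>> offs;
  int r = (int)std::floor(radius);
  for (int dx = -r; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy)
      for (int dz = -r; dz <= r; ++dz)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          offs.push_back({dx, dy, dz});

  std::vector<OlsModel> mdls;
  for (int k = 0; k < models.size(); ++k) {
    List mk = models[k];
    arma::mat X = as<arma::mat>(mk["X"]);
    arma::uvec rows = as<arma::uvec>(mk["rows"]) - 1;
    int focal = as<int>(mk["focal"]) - 1;
    mdls.push_back(make_model(X, rows, focal));
  }

  arma::mat out(V, mdls.size());
  out.fill(arma::datum::nan);
  std::vector<arma::uword> cols;
  cols.reserve(offs.size());

  for (int v = 0; v < V; ++v) {
    cols.clear();
    int cx = coords(v, 0) - 1, cy = coords(v, 1) - 1, cz = coords(v, 2) - 1;
    for (auto& o : offs) {
      int x = cx + o[0], y = cy + o[1], z = cz + o[2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      int col = lut[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
      if (col >= 0 && gray[col]) cols.push_back((arma::uword)col);
    }
    if ((int)cols.size() <= min_gray) continue;
    arma::uvec uc(cols);
    arma::vec z_pre = mean_z_pairs(pre.cols(uc), n_events, m);
    arma::vec z_post = mean_z_pairs(post.cols(uc), n_events, m);
    arma::vec change = z_post - z_pre;
    for (size_t k = 0; k < mdls.size(); ++k) {
      out(v, k) = focal_t(mdls[k], change);
    }
  }
  return out;
}

// ---- connected components (26-connectivity) --------------------------------

static IntegerVector components_26(const LogicalVector& mask,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    stack.push_back(s);
    labels[s] = next_label;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny), rem = cur % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            int t = xx + nx * (yy + ny * zz);
            if (mask[t] && labels[t] == 0) {
              labels[t] = next_label;
              stack.push_back(t);
            }
          }
    }
  }
  return labels;
}

// [[Rcpp::export]]
IntegerVector cpp_components(const LogicalVector& mask, const IntegerVector& dims) {
  return components_26(mask, dims);
}

// ---- TFCE ------------------------------------------------------------------

// Precomputed 26-neighbour lists over a set of "valid" voxels.
struct NeighborGraph {
  std::vector<std::vector<int>> nb;  // indices into the valid-voxel list
};

static NeighborGraph build_graph(const std::vector<int>& valid,
                                 const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> pos((size_t)nx * ny * nz, -1);
  for (size_t i = 0; i < valid.size(); ++i) pos[valid[i]] = (int)i;
  NeighborGraph g;
  g.nb.resize(valid.size());
  for (size_t i = 0; i < valid.size(); ++i) {
    int s = valid[i];
    int z = s / (nx * ny), rem = s % (nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int p = pos[xx + nx * (yy + ny * zz)];
          if (p >= 0) g.nb[i].push_back(p);
        }
  }
  return g;
}

// TFCE for the positive direction of `vals` (indexed over the graph's valid
// voxels). Voxels with value <= 0 get 0. Incremental union-find: process
// thresholds from high to low, merging clusters as voxels enter.
static void tfce_positive(const std::vector<double>& vals,
                          const NeighborGraph& g, double h_max, int n_steps,
                          double H, double E, std::vector<double>& out) {
  const size_t n = vals.size();
  std::fill(out.begin(), out.end(), 0.0);
  if (h_max <= 0) return;
  double dh = h_max / n_steps;

  std::vector<int> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return vals[a] > vals[b]; });

  std::vector<int> parent(n, -1), size(n, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };

  size_t ptr = 0;
  std::vector<int> active;  // voxels currently in the suprathreshold set
  active.reserve(n);
  for (int k = n_steps; k >= 1; --k) {
    double h = k * dh;
    while (ptr < n && vals[order[ptr]] >= h) {
      int v = order[ptr++];
      parent[v] = v;
      size[v] = 1;
      active.push_back(v);
      for (int u : g.nb[v]) {
        if (parent[u] != -1) {
          int ru = find(u), rv = find(v);
          if (ru != rv) {
            if (size[ru] < size[rv]) std::swap(ru, rv);
            parent[rv] = ru;
            size[ru] += size[rv];
          }
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (int v : active) {
      out[v] += std::pow((double)size[find(v)], E) * hH;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_tfce(const NumericVector& map, const IntegerVector& dims,
                       double H, double E, int n_steps) {
  const int n = map.size();
  std::vector<int> valid;
  for (int i = 0; i < n; ++i) {
    if (R_finite(map[i])) valid.push_back(i);
  }
  NeighborGraph g = build_graph(valid, dims);
  std::vector<double> vals(valid.size());
  double h_max = 0;
  for (size_t i = 0; i < valid.size(); ++i) {
    vals[i] = map[valid[i]];
    if (vals[i] > h_max) h_max = vals[i];
  }
  std::vector<double> out(valid.size(), 0.0);
  tfce_positive(vals, g, h_max, n_steps, H, E, out);
  NumericVector res(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(map[i])) res[i] = NA_REAL;
  }
  for (size_t i = 0; i < valid.size(); ++i) res[valid[i]] = out[i];
  return res;
}

// Two-sided TFCE statistic: enhancement of the positive and of the negated
// map (a voxel is nonzero in at most one direction).
static void tfce_two_sided(const std::vector<double>& tvals,
                           const NeighborGraph& g, int n_steps, double H,
                           double E, std::vector<double>& work,
                           std::vector<double>& out) {
  size_t n = tvals.size();
  double h_max_pos = 0, h_max_neg = 0;
  for (double v : tvals) {
    if (v > h_max_pos) h_max_pos = v;
    if (-v > h_max_neg) h_max_neg = -v;
  }
  tfce_positive(tvals, g, h_max_pos, n_steps, H, E, out);
  std::vector<double> neg(n);
  for (size_t i = 0; i < n; ++i) neg[i] = -tvals[i];
  tfce_positive(neg, g, h_max_neg, n_steps, H, E, work);
  for (size_t i = 0; i < n; ++i) out[i] += work[i];
}

// Group-level sign-flip test on per-subject maps with two-sided TFCE and
// max-statistic small-volume correction.
// maps: S x V (V = prod(dims), column-major volume). svc: logical V.
// [[Rcpp::export]]
List cpp_group_map_test(const arma::mat& maps, const IntegerVector& dims,
                        const LogicalVector& svc, double H, double E,
                        int n_steps, int n_flips) {
  const int S = maps.n_rows, V = maps.n_cols;

  // valid voxels: finite for every subject
  std::vector<int> valid;
  for (int v = 0; v < V; ++v) {
    bool ok = true;
    for (int s = 0; s < S; ++s) {
      if (!R_finite(maps(s, v))) { ok = false; break; }
    }
    if (ok) valid.push_back(v);
  }
  const size_t nv = valid.size();
  if (nv == 0) stop("no voxel has valid values for every subject");
  NeighborGraph g = build_graph(valid, dims);

  arma::mat X(S, nv);
  for (size_t i = 0; i < nv; ++i) X.col(i) = maps.col(valid[i]);
  arma::rowvec ssq = arma::sum(arma::square(X), 0);

  auto tstat = [&](const arma::vec& signs, std::vector<double>& t) {
    arma::rowvec m = (signs.t() * X) / S;
    for (size_t i = 0; i < nv; ++i) {
      double var = (ssq(i) - S * m(i) * m(i)) / (S - 1);
      t[i] = var > 0 ? m(i) / std::sqrt(var / S) : 0.0;
    }
  };

  std::vector<double> t_obs(nv), tfce_obs(nv), work(nv), t_flip(nv), tfce_flip(nv);
  arma::vec ones(S, arma::fill::ones);
  tstat(ones, t_obs);
  tfce_two_sided(t_obs, g, n_steps, H, E, work, tfce_obs);

  std::vector<bool> in_svc(nv);
  for (size_t i = 0; i < nv; ++i) in_svc[i] = svc[valid[i]];

  std::vector<int> cnt_corr(nv, 0), cnt_unc(nv, 0);
  GetRNGstate();
  for (int f = 0; f < n_flips; ++f) {
    arma::vec signs(S);
    for (int s = 0; s < S; ++s) signs(s) = unif_rand() < 0.5 ? -1.0 : 1.0;
    tstat(signs, t_flip);
    tfce_two_sided(t_flip, g, n_steps, H, E, work, tfce_flip);
    double mx = 0;
    for (size_t i = 0; i < nv; ++i) {
      if (in_svc[i] && tfce_flip[i] > mx) mx = tfce_flip[i];
      // voxelwise uncorrected p on the same TFCE statistic (as FSL
      // randomise does), so corrected >= uncorrected everywhere in the mask
      if (tfce_flip[i] >= tfce_obs[i]) ++cnt_unc[i];
    }
    for (size_t i = 0; i < nv; ++i) {
      if (mx >= tfce_obs[i]) ++cnt_corr[i];
    }
  }
  PutRNGstate();

  NumericVector t_out(V, NA_REAL), tfce_out(V, NA_REAL),
      p_corr(V, NA_REAL), p_unc(V, NA_REAL);
  for (size_t i = 0; i < nv; ++i) {
    int v = valid[i];
    t_out[v] = t_obs[i];
    tfce_out[v] = tfce_obs[i];
    p_unc[v] = (1.0 + cnt_unc[i]) / (1.0 + n_flips);
    if (in_svc[i]) p_corr[v] = (1.0 + cnt_corr[i]) / (1.0 + n_flips);
  }
  return List::create(_["t"] = t_out, _["tfce"] = tfce_out,
                      _["p_corrected"] = p_corr, _["p_uncorrected"] = p_unc);
}
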