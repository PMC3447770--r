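// Batched settling engine: cycles of net-input -> kWTA -> membrane step ->
// rate activation, with patterns as matrix columns. Mirrors the layer /
// projection structures built in R. Two performance points: projection
// weights are transposed once per call so every product is a plain
// column-major multiply, and source layers whose kWTA code is sparse are
// multiplied as sparse matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// k-th and (k+1)-th largest alive entry of the threshold-conductance column.
static void top_two_at_k(const std::vector<double>& buf, int k,
                         double& sk, double& sk1) {
  std::vector<double> b(buf);
  std::nth_element(b.begin(), b.begin() + (k - 1), b.end(),
                   std::greater<double>());
  sk = b[k - 1];
  sk1 = *std::max_element(b.begin() + k, b.end());
}

// [[Rcpp::export(name = ".settle_engine")]]
List settle_engine(List acts_in,        // per-layer activation matrices (n x P)
                   LogicalVector is_free,
                   List bias,           // per-layer bias vectors
                   List alive,          // per-layer logical vectors
                   IntegerVector kvec,  // per-layer kWTA k
                   List proj_src, List proj_dst, List proj_scale,
                   List proj_sign, List proj_W,
                   int cycles, double tau, double gain, double threshold,
                   double gb_e, double gb_l, double gb_i,
                   double E_e, double E_l, double E_i,
                   int track = -1) {
  const int L = acts_in.size();
  const int NP = proj_W.size();
  std::vector<arma::mat> act(L), vm(L);
  std::vector<arma::uvec> alive_idx(L), dead_idx(L);
  std::vector<arma::vec> bias_v(L);
  int P = 0;

  for (int l = 0; l < L; ++l) {
    act[l] = as<arma::mat>(acts_in[l]);
    P = act[l].n_cols;
    bias_v[l] = as<arma::vec>(bias[l]);
    LogicalVector al = alive[l];
    std::vector<arma::uword> av, dv;
    for (int i = 0; i < al.size(); ++i) {
      if (al[i]) av.push_back(i); else dv.push_back(i);
    }
    alive_idx[l] = arma::uvec(av);
    dead_idx[l] = arma::uvec(dv);
    if (is_free[l]) {
      vm[l].set_size(act[l].n_rows, P);
      vm[l].fill(E_l);
    }
  }

  std::vector<int> psrc(NP), pdst(NP);
  std::vector<double> pscale(NP), psign(NP);
  std::vector<arma::mat> Wt(NP);  // transposed weights: n_dst x n_src
  for (int p = 0; p < NP; ++p) {
    psrc[p] = as<int>(proj_src[p]);
    pdst[p] = as<int>(proj_dst[p]);
    pscale[p] = as<double>(proj_scale[p]);
    psign[p] = as<double>(proj_sign[p]);
    Wt[p] = arma::trans(as<arma::mat>(proj_W[p]));
  }

  // contributions from clamped source layers are constant across cycles
  std::vector<arma::mat> static_ge(L), static_gi(L);
  for (int l = 0; l < L; ++l) {
    if (!is_free[l]) continue;
    static_ge[l] = arma::repmat(bias_v[l], 1, P);
    static_gi[l] = arma::zeros<arma::mat>(act[l].n_rows, P);
    for (int p = 0; p < NP; ++p) {
      if (pdst[p] != l || is_free[psrc[p]]) continue;
      if (psign[p] > 0) static_ge[l] += pscale[p] * (Wt[p] * act[psrc[p]]);
      else              static_gi[l] += pscale[p] * (Wt[p] * act[psrc[p]]);
    }
  }

  // which free layers feed other free layers (need per-cycle products)
  std::vector<bool> is_dyn_source(L, false);
  for (int p = 0; p < NP; ++p)
    if (is_free[psrc[p]] && is_free[pdst[p]]) is_dyn_source[psrc[p]] = true;

  const double E_min = std::min(E_i, std::min(E_l, E_e));
  const double E_max = std::max(E_i, std::max(E_l, E_e));
  const double denom = (threshold - E_i) * gb_i;
  const double ce = gb_e * (E_e - threshold);
  const double cl = gb_l * (E_l - threshold);
  const double ci = gb_i * (E_i - threshold);

  std::vector<arma::sp_mat> sp(L);
  std::vector<bool> use_sp(L, false);
  std::vector<arma::mat> newy(L);
  List history(track >= 0 ? cycles : 0);

  for (int cyc = 0; cyc < cycles; ++cyc) {
    // sparse views of sparse-coded source layers
    for (int l = 0; l < L; ++l) {
      if (!is_dyn_source[l]) continue;
      double nnz = arma::accu(act[l] != 0);
      use_sp[l] = nnz < 0.25 * act[l].n_elem;
      if (use_sp[l]) sp[l] = arma::sp_mat(act[l]);
    }
    for (int l = 0; l < L; ++l) {
      if (!is_free[l]) continue;
      const int n = act[l].n_rows;
      arma::mat ge = static_ge[l];
      arma::mat gi = static_gi[l];
      for (int p = 0; p < NP; ++p) {
        if (pdst[p] != l || !is_free[psrc[p]]) continue;
        arma::mat& tgt = (psign[p] > 0) ? ge : gi;
        if (use_sp[psrc[p]]) tgt += pscale[p] * (Wt[p] * sp[psrc[p]]);
        else                 tgt += pscale[p] * (Wt[p] * act[psrc[p]]);
      }
      const int n_alive = alive_idx[l].n_elem;
      int k = std::min<int>(kvec[l], n_alive);
      arma::rowvec gik(P, arma::fill::zeros);
      if (n_alive > 0 && k < n_alive) {
        std::vector<double> buf(n_alive);
        for (int j = 0; j < P; ++j) {
          for (int ii = 0; ii < n_alive; ++ii) {
            const arma::uword i = alive_idx[l](ii);
            buf[ii] = (ge(i, j) * ce + cl + gi(i, j) * ci) / denom;
          }
          double g;
          if (k <= 0) {
            g = std::max(*std::max_element(buf.begin(), buf.end()), 0.0) + 1.0;
          } else {
            double sk, sk1;
            top_two_at_k(buf, k, sk, sk1);
            g = std::max((sk + sk1) / 2.0, 0.0);
          }
          gik(j) = g;
        }
      }
      arma::mat& v = vm[l];
      arma::mat y(n, P);
      for (int j = 0; j < P; ++j) {
        const double gkj = gik(j);
        for (int i = 0; i < n; ++i) {
          const double gei = ge(i, j);
          const double gii = gi(i, j) + gkj;
          const double G = gei * gb_e + gb_l + gii * gb_i;
          const double num = gei * gb_e * E_e + gb_l * E_l + gii * gb_i * E_i;
          double a = tau * G;
          if (a > 1.0) a = 1.0;
          double vv = v(i, j) + a * (num / G - v(i, j));
          if (!std::isfinite(vv))
            stop("settling-failure: non-finite state at cycle %d", cyc + 1);
          if (vv < E_min) vv = E_min;
          if (vv > E_max) vv = E_max;
          v(i, j) = vv;
          const double d = vv - threshold;
          y(i, j) = (d <= 0) ? 0.0 : (2.0 / (1.0 + std::exp(-gain * d)) - 1.0);
        }
      }
      for (arma::uword ii = 0; ii < dead_idx[l].n_elem; ++ii)
        y.row(dead_idx[l](ii)).zeros();
      newy[l] = std::move(y);
    }
    for (int l = 0; l < L; ++l)
      if (is_free[l]) act[l] = std::move(newy[l]);
    if (track >= 0) history[cyc] = wrap(act[track]);
  }

  List out_act(L), out_vm(L);
  for (int l = 0; l < L; ++l) {
    out_act[l] = wrap(act[l]);
    out_vm[l] = is_free[l] ? wrap(vm[l]) : R_NilValue;
  }
  return List::create(_["act"] = out_act, _["vm"] = out_vm,
                      _["history"] = history);
}
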