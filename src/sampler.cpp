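// Blocked Gibbs sampler for the hierarchical height model.
//
// Effects are updated unit by unit (world block, then each super-region,
// region and country) from their exact multivariate-normal full
// conditionals given the variances; each unit block holds its intercept
// and slope deviation together with its RW2 vector, whose sum-to-zero and
// zero-linear-moment constraints are imposed exactly by a kriging
// correction. Deviation, RW2 and study-offset variances have conjugate
// inverse-gamma/gamma updates; the residual variances (global and
// non-national extra) enter the likelihood added to row-specific sampling
// variances and are updated by log-scale random-walk Metropolis.
//
// All randomness comes from R's RNG so draws are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Obs {
  vec y, se2, dt, a18, w;   // w: interpolation weight on upper grid point
  uvec i0;                  // lower grid index (0-based)
  uvec country, region, super, cov; // cov: 0 nat, 1 subnat, 2 community
  ivec study;               // offset-study index (-1 = national)
};

double rnorm1() { return R::rnorm(0.0, 1.0); }

// inverse-gamma draw, shape a, scale b
double rinvgamma(double a, double b) { return 1.0 / R::rgamma(a, 1.0 / b); }

double dinvgamma_log(double x, double a, double b) {
  return a * std::log(b) - std::lgamma(a) - (a + 1.0) * std::log(x) - b / x;
}

class Sampler {
public:
  int K, nC, nR, nS, nB, nObs;
  bool use_rw2, use_offsets;
  Obs obs;
  uvec region_of_country, super_of_region, super_of_country;
  ivec b_level;             // per offset study: 1 subnat, 2 community
  vec dtgrid;               // grid cohort minus t0
  mat Krw;                  // RW2 structure matrix (K x K)
  mat Cc;                   // 2 x K constraint matrix
  mat CtC;                  // K x K, Cc' * Cc

  // state
  double alpha0, beta0, gamma_;
  vec ag, ar, ac, bg, br, bc;
  vec uglob;
  mat ug, ur, uc;
  vec b;
  vec s2a, s2b;             // length 3: super, region, country
  vec rwv;                  // length 4: world, super, region, country
  vec tau2, nu2;            // length 2: subnational, community
  double omega2;

  // priors
  double alpha0_mean, alpha0_var, beta0_var, gamma_var;
  vec ig_s2a, ig_s2b, ig_rwv, ig_tau2, ig_nu2, ig_om; // (shape, scale)
  bool fix_s2a, fix_s2b, fix_rwv, fix_tau2, fix_nu2, fix_om;
  double mh_step;

  // bookkeeping
  vec r;                    // residual y - eta
  vec vinv;                 // 1 / (se2 + omega2 + nu2[cov])
  std::vector<uvec> super_obs, region_obs, country_obs, study_obs;
  int mh_prop = 0, mh_acc = 0;

  void refresh_vinv() {
    for (int i = 0; i < nObs; ++i) {
      double v = obs.se2[i] + omega2;
      if (obs.cov[i] == 1) v += nu2[0];
      else if (obs.cov[i] == 2) v += nu2[1];
      vinv[i] = 1.0 / v;
    }
  }

  // contribution of a unit's coefficients to observation i
  // theta layout: [alpha, beta, (gamma if global), u(K if use_rw2)]
  double unit_contrib(const vec& th, int i, bool global) const {
    int p = global ? 3 : 2;
    double c = th[0] + th[1] * obs.dt[i];
    if (global) c += th[2] * obs.a18[i];
    if (use_rw2) {
      int j = obs.i0[i];
      c += th[p + j] * (1.0 - obs.w[i]) + th[p + j + 1] * obs.w[i];
    }
    return c;
  }

  // sample a unit block from its Gaussian full conditional
  void update_unit(vec& th, const uvec& idx, bool global,
                   double prec_a, double rhs_a, double prec_b,
                   double prec_g, double rw_prec) {
    int p = global ? 3 : 2;
    int d = p + (use_rw2 ? K : 0);
    mat A(d, d, fill::zeros);
    vec rhs(d, fill::zeros);

    A(0, 0) = prec_a; rhs[0] = rhs_a;
    A(1, 1) = prec_b;
    if (global) A(2, 2) = prec_g;
    if (use_rw2) {
      A.submat(p, p, d - 1, d - 1) = rw_prec * (Krw + CtC);
    }

    // likelihood terms on partial residuals
    for (uword t = 0; t < idx.n_elem; ++t) {
      int i = idx[t];
      double pr = r[i] + unit_contrib(th, i, global);
      double wt = vinv[i];
      double x1 = obs.dt[i];
      A(0, 0) += wt; A(0, 1) += wt * x1; A(1, 1) += wt * x1 * x1;
      rhs[0] += wt * pr; rhs[1] += wt * x1 * pr;
      if (global) {
        double x2 = obs.a18[i];
        A(0, 2) += wt * x2; A(1, 2) += wt * x1 * x2; A(2, 2) += wt * x2 * x2;
        rhs[2] += wt * x2 * pr;
      }
      if (use_rw2) {
        int j0 = p + obs.i0[i];
        double wa = 1.0 - obs.w[i], wb = obs.w[i];
        A(0, j0) += wt * wa; A(0, j0 + 1) += wt * wb;
        A(1, j0) += wt * x1 * wa; A(1, j0 + 1) += wt * x1 * wb;
        if (global) {
          double x2 = obs.a18[i];
          A(2, j0) += wt * x2 * wa; A(2, j0 + 1) += wt * x2 * wb;
        }
        A(j0, j0) += wt * wa * wa;
        A(j0, j0 + 1) += wt * wa * wb;
        A(j0 + 1, j0 + 1) += wt * wb * wb;
        rhs[j0] += wt * wa * pr; rhs[j0 + 1] += wt * wb * pr;
      }
    }
    A = symmatu(A);

    mat R_ = chol(A); // upper: A = R'R
    vec mu = solve(trimatu(R_), solve(trimatl(R_.t()), rhs));
    vec z(d); for (int j = 0; j < d; ++j) z[j] = rnorm1();
    vec draw = mu + solve(trimatu(R_), z);

    if (use_rw2) {
      // exact constraint via kriging correction: condition on C u = 0
      mat Cf(2, d, fill::zeros);
      Cf.cols(p, d - 1) = Cc;
      mat M = solve(trimatu(R_), solve(trimatl(R_.t()), Cf.t())); // d x 2
      mat S = Cf * M;                                             // 2 x 2
      vec viol = Cf * draw;
      draw -= M * solve(S, viol);
    }

    vec old = th;
    th = draw;
    for (uword t = 0; t < idx.n_elem; ++t) {
      int i = idx[t];
      r[i] -= unit_contrib(th, i, global) - unit_contrib(old, i, global);
    }
  }

  void update_effects() {
    // world block: alpha0, beta0, gamma, u_glob
    {
      uvec all = regspace<uvec>(0, nObs - 1);
      int d = 3 + (use_rw2 ? K : 0);
      vec th(d, fill::zeros);
      th[0] = alpha0; th[1] = beta0; th[2] = gamma_;
      if (use_rw2) th.subvec(3, d - 1) = uglob;
      update_unit(th, all, true, 1.0 / alpha0_var, alpha0_mean / alpha0_var,
                  1.0 / beta0_var, 1.0 / gamma_var,
                  use_rw2 ? 1.0 / rwv[0] : 0.0);
      alpha0 = th[0]; beta0 = th[1]; gamma_ = th[2];
      if (use_rw2) uglob = th.subvec(3, d - 1);
    }
    auto level_pass = [&](int n, const std::vector<uvec>& obs_of,
                          vec& a, vec& bsl, mat& u, double s2a_l,
                          double s2b_l, double rwv_l) {
      int d = 2 + (use_rw2 ? K : 0);
      for (int g = 0; g < n; ++g) {
        vec th(d, fill::zeros);
        th[0] = a[g]; th[1] = bsl[g];
        if (use_rw2) th.subvec(2, d - 1) = u.col(g);
        update_unit(th, obs_of[g], false, 1.0 / s2a_l, 0.0, 1.0 / s2b_l,
                    0.0, use_rw2 ? 1.0 / rwv_l : 0.0);
        a[g] = th[0]; bsl[g] = th[1];
        if (use_rw2) u.col(g) = th.subvec(2, d - 1);
      }
    };
    level_pass(nS, super_obs, ag, bg, ug, s2a[0], s2b[0], rwv[1]);
    level_pass(nR, region_obs, ar, br, ur, s2a[1], s2b[1], rwv[2]);
    level_pass(nC, country_obs, ac, bc, uc, s2a[2], s2b[2], rwv[3]);

    if (use_offsets) {
      for (int j = 0; j < nB; ++j) {
        const uvec& idx = study_obs[j];
        double prec = 1.0 / tau2[b_level[j] - 1];
        double rhs = 0.0;
        for (uword t = 0; t < idx.n_elem; ++t) {
          int i = idx[t];
          double pr = r[i] + b[j];
          prec += vinv[i];
          rhs += vinv[i] * pr;
        }
        double old = b[j];
        b[j] = rhs / prec + rnorm1() / std::sqrt(prec);
        for (uword t = 0; t < idx.n_elem; ++t) r[idx[t]] -= b[j] - old;
      }
    }
  }

  // Children of each unit in the nesting (filled in setup).
  std::vector<std::vector<int>> regions_of_super, countries_of_region;

  // Translation sweeps: the likelihood only identifies sums across the
  // hierarchy levels (a balanced shift of a parent level against its
  // children leaves every fitted mean unchanged), so those directions mix
  // slowly under per-unit updates. Each sweep is an extra Gibbs step on
  // the shift, whose full conditional under the prior is Gaussian; the
  // likelihood is exactly invariant along it.
  void sweep_pair_scalar(double& parent, double parent_mean,
                         double parent_var, vec& child,
                         const std::vector<int>& kids, double child_var) {
    double prec = 1.0 / parent_var + kids.size() / child_var;
    double num = (parent_mean - parent) / parent_var;
    for (int j : kids) num += child[j] / child_var;
    double d = num / prec + rnorm1() / std::sqrt(prec);
    parent += d;
    for (int j : kids) child[j] -= d;
  }

  void sweep_pair_vec(vec& parent, double parent_rwv, mat& child,
                      const std::vector<int>& kids, double child_rwv) {
    double kp = 1.0 / parent_rwv, kc = 1.0 / child_rwv;
    vec csum(K, fill::zeros);
    for (int j : kids) csum += child.col(j);
    vec rhs = Krw * (kc * csum - kp * parent);
    mat A = (kp + kids.size() * kc) * (Krw + CtC);
    mat R_ = chol(A);
    vec mu = solve(trimatu(R_), solve(trimatl(R_.t()), rhs));
    vec z(K); for (int j = 0; j < K; ++j) z[j] = rnorm1();
    vec d = mu + solve(trimatu(R_), z);
    mat M = solve(trimatu(R_), solve(trimatl(R_.t()), Cc.t()));
    d -= M * solve(Cc * M, Cc * d);
    parent += d;
    for (int j : kids) child.col(j) -= d;
  }

  void translation_sweeps() {
    std::vector<int> all_s(nS), all_r(nR);
    for (int g = 0; g < nS; ++g) all_s[g] = g;
    sweep_pair_scalar(alpha0, alpha0_mean, alpha0_var, ag, all_s, s2a[0]);
    sweep_pair_scalar(beta0, 0.0, beta0_var, bg, all_s, s2b[0]);
    for (int g = 0; g < nS; ++g) {
      sweep_pair_scalar(ag[g], 0.0, s2a[0], ar, regions_of_super[g], s2a[1]);
      sweep_pair_scalar(bg[g], 0.0, s2b[0], br, regions_of_super[g], s2b[1]);
    }
    for (int rg = 0; rg < nR; ++rg) {
      sweep_pair_scalar(ar[rg], 0.0, s2a[1], ac, countries_of_region[rg],
                        s2a[2]);
      sweep_pair_scalar(br[rg], 0.0, s2b[1], bc, countries_of_region[rg],
                        s2b[2]);
    }
    if (use_rw2) {
      sweep_pair_vec(uglob, rwv[0], ug, all_s, rwv[1]);
      for (int g = 0; g < nS; ++g) {
        vec tmp = ug.col(g);
        sweep_pair_vec(tmp, rwv[1], ur, regions_of_super[g], rwv[2]);
        ug.col(g) = tmp;
      }
      for (int rg = 0; rg < nR; ++rg) {
        vec tmp = ur.col(rg);
        sweep_pair_vec(tmp, rwv[2], uc, countries_of_region[rg], rwv[3]);
        ur.col(rg) = tmp;
      }
    }
  }

  void update_conjugate_variances() {
    if (!fix_s2a) {
      s2a[0] = rinvgamma(ig_s2a[0] + nS / 2.0, ig_s2a[1] + dot(ag, ag) / 2.0);
      s2a[1] = rinvgamma(ig_s2a[0] + nR / 2.0, ig_s2a[1] + dot(ar, ar) / 2.0);
      s2a[2] = rinvgamma(ig_s2a[0] + nC / 2.0, ig_s2a[1] + dot(ac, ac) / 2.0);
    }
    if (!fix_s2b) {
      s2b[0] = rinvgamma(ig_s2b[0] + nS / 2.0, ig_s2b[1] + dot(bg, bg) / 2.0);
      s2b[1] = rinvgamma(ig_s2b[0] + nR / 2.0, ig_s2b[1] + dot(br, br) / 2.0);
      s2b[2] = rinvgamma(ig_s2b[0] + nC / 2.0, ig_s2b[1] + dot(bc, bc) / 2.0);
    }
    if (use_rw2 && !fix_rwv) {
      double halfrank = (K - 2) / 2.0;
      auto qf = [&](const vec& u) { return as_scalar(u.t() * Krw * u); };
      rwv[0] = rinvgamma(ig_rwv[0] + halfrank, ig_rwv[1] + qf(uglob) / 2.0);
      auto level_q = [&](const mat& u) {
        double q = 0.0;
        for (uword g = 0; g < u.n_cols; ++g) q += qf(u.col(g));
        return q;
      };
      rwv[1] = rinvgamma(ig_rwv[0] + nS * halfrank,
                         ig_rwv[1] + level_q(ug) / 2.0);
      rwv[2] = rinvgamma(ig_rwv[0] + nR * halfrank,
                         ig_rwv[1] + level_q(ur) / 2.0);
      rwv[3] = rinvgamma(ig_rwv[0] + nC * halfrank,
                         ig_rwv[1] + level_q(uc) / 2.0);
    }
    if (use_offsets && !fix_tau2 && nB > 0) {
      for (int l = 1; l <= 2; ++l) {
        double ss = 0.0; int m = 0;
        for (int j = 0; j < nB; ++j) {
          if (b_level[j] == l) { ss += b[j] * b[j]; ++m; }
        }
        if (m > 0) tau2[l - 1] = rinvgamma(ig_tau2[0] + m / 2.0,
                                           ig_tau2[1] + ss / 2.0);
      }
    }
  }

  // residual log-likelihood as a function of candidate variance params
  double resid_loglik(double om, double nsn, double ncm) const {
    double ll = 0.0;
    for (int i = 0; i < nObs; ++i) {
      double v = obs.se2[i] + om;
      if (obs.cov[i] == 1) v += nsn;
      else if (obs.cov[i] == 2) v += ncm;
      ll += -0.5 * (std::log(v) + r[i] * r[i] / v);
    }
    return ll;
  }

  void mh_variance(double& par, const vec& ig, int which) {
    // which: 0 omega2, 1 nu2_sn, 2 nu2_comm
    double cur = par;
    double prop = cur * std::exp(mh_step * rnorm1());
    double om = omega2, nsn = nu2[0], ncm = nu2[1];
    double om_p = om, nsn_p = nsn, ncm_p = ncm;
    if (which == 0) om_p = prop;
    else if (which == 1) nsn_p = prop;
    else ncm_p = prop;
    double lacc = resid_loglik(om_p, nsn_p, ncm_p) -
      resid_loglik(om, nsn, ncm) +
      dinvgamma_log(prop, ig[0], ig[1]) - dinvgamma_log(cur, ig[0], ig[1]) +
      std::log(prop) - std::log(cur); // log-scale proposal Jacobian
    ++mh_prop;
    if (std::log(R::unif_rand()) < lacc) { par = prop; ++mh_acc; }
  }

  void update_residual_variances() {
    if (!fix_om) mh_variance(omega2, ig_om, 0);
    if (!fix_nu2) {
      mh_variance(nu2[0], ig_nu2, 1);
      mh_variance(nu2[1], ig_nu2, 2);
    }
    refresh_vinv();
  }

  mat country_curves() const {
    mat out(nC, K);
    for (int c = 0; c < nC; ++c) {
      int rg = region_of_country[c], sp = super_of_country[c];
      double lev = alpha0 + ag[sp] + ar[rg] + ac[c];
      double slp = beta0 + bg[sp] + br[rg] + bc[c];
      for (int k = 0; k < K; ++k) {
        double v = lev + slp * dtgrid[k];
        if (use_rw2) v += uglob[k] + ug(k, sp) + ur(k, rg) + uc(k, c);
        out(c, k) = v;
      }
    }
    return out;
  }

  vec flat_state() const {
    int d = 3 + 2 * (nS + nR + nC) + (use_rw2 ? K * (1 + nS + nR + nC) : 0) +
      nB;
    vec s(d);
    int p = 0;
    s[p++] = alpha0; s[p++] = beta0; s[p++] = gamma_;
    auto put = [&](const vec& v) { s.subvec(p, p + v.n_elem - 1) = v; p += v.n_elem; };
    put(ag); put(ar); put(ac); put(bg); put(br); put(bc);
    if (use_rw2) { put(uglob); put(vectorise(ug)); put(vectorise(ur)); put(vectorise(uc)); }
    if (nB > 0) put(b);
    return s;
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List run_chain_cpp(Rcpp::List dat, Rcpp::List init, Rcpp::List prior,
                         Rcpp::List control) {
  Sampler s;
  s.K = Rcpp::as<int>(dat["K"]);
  s.nC = Rcpp::as<int>(dat["nC"]);
  s.nR = Rcpp::as<int>(dat["nR"]);
  s.nS = Rcpp::as<int>(dat["nS"]);
  s.nB = Rcpp::as<int>(dat["nB"]);
  s.use_rw2 = Rcpp::as<bool>(dat["use_rw2"]);
  s.use_offsets = Rcpp::as<bool>(dat["use_offsets"]);

  s.obs.y = Rcpp::as<vec>(dat["y"]);
  s.obs.se2 = Rcpp::as<vec>(dat["se2"]);
  s.obs.dt = Rcpp::as<vec>(dat["dt"]);
  s.obs.a18 = Rcpp::as<vec>(dat["a18"]);
  s.obs.w = Rcpp::as<vec>(dat["w"]);
  s.obs.i0 = Rcpp::as<uvec>(dat["i0"]);
  s.obs.country = Rcpp::as<uvec>(dat["country"]);
  s.obs.cov = Rcpp::as<uvec>(dat["cov"]);
  s.obs.study = Rcpp::as<ivec>(dat["study"]);
  s.nObs = s.obs.y.n_elem;

  s.region_of_country = Rcpp::as<uvec>(dat["region_of_country"]);
  s.super_of_region = Rcpp::as<uvec>(dat["super_of_region"]);
  s.super_of_country = Rcpp::as<uvec>(dat["super_of_country"]);
  s.b_level = Rcpp::as<ivec>(dat["b_level"]);
  s.dtgrid = Rcpp::as<vec>(dat["dtgrid"]);

  // RW2 structure and constraint matrices
  {
    mat D(s.K - 2, s.K, fill::zeros);
    for (int i = 0; i < s.K - 2; ++i) {
      D(i, i) = 1; D(i, i + 1) = -2; D(i, i + 2) = 1;
    }
    s.Krw = D.t() * D;
    s.Cc.set_size(2, s.K);
    for (int k = 0; k < s.K; ++k) {
      s.Cc(0, k) = 1.0;
      s.Cc(1, k) = (k + 1) - (s.K + 1) / 2.0;
    }
    s.CtC = s.Cc.t() * s.Cc;
  }

  // observation lists per unit
  s.obs.region.set_size(s.nObs); s.obs.super.set_size(s.nObs);
  std::vector<std::vector<uword>> so(s.nS), ro(s.nR), co(s.nC), bo(s.nB);
  for (int i = 0; i < s.nObs; ++i) {
    int c = s.obs.country[i];
    int rg = s.region_of_country[c];
    int sp = s.super_of_country[c];
    s.obs.region[i] = rg; s.obs.super[i] = sp;
    co[c].push_back(i); ro[rg].push_back(i); so[sp].push_back(i);
    if (s.obs.study[i] >= 0) bo[s.obs.study[i]].push_back(i);
  }
  auto to_uvecs = [](std::vector<std::vector<uword>>& v) {
    std::vector<uvec> out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = uvec(v[i]);
    return out;
  };
  s.super_obs = to_uvecs(so); s.region_obs = to_uvecs(ro);
  s.country_obs = to_uvecs(co); s.study_obs = to_uvecs(bo);

  s.regions_of_super.assign(s.nS, {});
  for (int rg = 0; rg < s.nR; ++rg) {
    s.regions_of_super[s.super_of_region[rg]].push_back(rg);
  }
  s.countries_of_region.assign(s.nR, {});
  for (int c = 0; c < s.nC; ++c) {
    s.countries_of_region[s.region_of_country[c]].push_back(c);
  }

  // priors
  s.alpha0_mean = Rcpp::as<double>(prior["alpha0_mean"]);
  s.alpha0_var = Rcpp::as<double>(prior["alpha0_var"]);
  s.beta0_var = Rcpp::as<double>(prior["beta0_var"]);
  s.gamma_var = Rcpp::as<double>(prior["gamma_var"]);
  s.ig_s2a = Rcpp::as<vec>(prior["sigma2_alpha_prior"]);
  s.ig_s2b = Rcpp::as<vec>(prior["sigma2_beta_prior"]);
  s.ig_rwv = Rcpp::as<vec>(prior["rw2_var_prior"]);
  s.ig_tau2 = Rcpp::as<vec>(prior["tau2_prior"]);
  s.ig_nu2 = Rcpp::as<vec>(prior["nu2_prior"]);
  s.ig_om = Rcpp::as<vec>(prior["omega2_prior"]);

  Rcpp::LogicalVector fx = control["fixed"];
  s.fix_s2a = fx["sigma2_alpha"]; s.fix_s2b = fx["sigma2_beta"];
  s.fix_rwv = fx["rw2_var"]; s.fix_tau2 = fx["tau2"];
  s.fix_nu2 = fx["nu2"]; s.fix_om = fx["omega2"];
  s.mh_step = Rcpp::as<double>(control["mh_step"]);

  // initial state
  s.alpha0 = Rcpp::as<double>(init["alpha0"]);
  s.beta0 = 0.0; s.gamma_ = 0.0;
  s.ag.zeros(s.nS); s.ar.zeros(s.nR); s.ac.zeros(s.nC);
  s.bg.zeros(s.nS); s.br.zeros(s.nR); s.bc.zeros(s.nC);
  s.uglob.zeros(s.K);
  s.ug.zeros(s.K, s.nS); s.ur.zeros(s.K, s.nR); s.uc.zeros(s.K, s.nC);
  s.b.zeros(s.nB);
  s.s2a = Rcpp::as<vec>(init["sigma2_alpha"]);
  s.s2b = Rcpp::as<vec>(init["sigma2_beta"]);
  s.rwv = Rcpp::as<vec>(init["rw2_var"]);
  s.tau2 = Rcpp::as<vec>(init["tau2"]);
  s.nu2 = Rcpp::as<vec>(init["nu2"]);
  s.omega2 = Rcpp::as<double>(init["omega2"]);

  s.r = s.obs.y - s.alpha0; // eta starts at alpha0 (all else zero)
  s.vinv.set_size(s.nObs);
  s.refresh_vinv();

  int n_burnin = Rcpp::as<int>(control["n_burnin"]);
  int n_samples = Rcpp::as<int>(control["n_samples"]);
  int thin = Rcpp::as<int>(control["thin"]);
  bool monitor_state = Rcpp::as<bool>(control["monitor_state"]);

  int n_iter = n_burnin + n_samples * thin;
  mat curves(s.nC * s.K, n_samples); // column-major: country varies fastest
  mat vdraw(18, n_samples);          // scalar monitors, see fit.R for names
  mat state;
  if (monitor_state) {
    state.set_size(s.flat_state().n_elem, n_samples);
  }

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    s.update_effects();
    s.translation_sweeps();
    s.update_conjugate_variances();
    s.update_residual_variances();
    if (it >= n_burnin && ((it - n_burnin + 1) % thin == 0)) {
      mat cc = s.country_curves();
      curves.col(kept) = vectorise(cc); // country-major? vectorise: col-major
      vec v(18);
      v[0] = s.alpha0; v[1] = s.beta0; v[2] = s.gamma_;
      v[3] = s.s2a[0]; v[4] = s.s2a[1]; v[5] = s.s2a[2];
      v[6] = s.s2b[0]; v[7] = s.s2b[1]; v[8] = s.s2b[2];
      v[9] = s.rwv[0]; v[10] = s.rwv[1]; v[11] = s.rwv[2]; v[12] = s.rwv[3];
      v[13] = s.tau2[0]; v[14] = s.tau2[1];
      v[15] = s.nu2[0]; v[16] = s.nu2[1]; v[17] = s.omega2;
      vdraw.col(kept) = v;
      if (monitor_state) state.col(kept) = s.flat_state();
      ++kept;
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("curves") = curves,
    Rcpp::Named("scalars") = vdraw,
    Rcpp::Named("mh_accept_rate") =
      s.mh_prop > 0 ? (double)s.mh_acc / s.mh_prop : NA_REAL);
  if (monitor_state) out["state"] = state;
  return out;
}
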