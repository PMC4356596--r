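#include <Rcpp.h>
using namespace Rcpp;

// Mass-action right-hand side.  Reactions have 0-2 reactants (indices r1,
// r2; 0 = absent, so a zero-order source has r1 = r2 = 0) and a net
// stoichiometry given in triplet form (species s_sp, reaction s_rx,
// coefficient s_co).  Flux of reaction j is k[j] * x[r1] * x[r2]; a doubled
// reactant (r1 == r2) therefore contributes k * x^2.

static void masact_rhs(int n, int nr, const double *x, const double *k,
                       const int *r1, const int *r2,
                       int nt, const int *s_sp, const int *s_rx,
                       const double *s_co, double *flux, double *dx) {
  for (int j = 0; j < nr; ++j) {
    double f = k[j];
    if (r1[j] > 0) f *= x[r1[j] - 1];
    if (r2[j] > 0) f *= x[r2[j] - 1];
    flux[j] = f;
  }
  for (int s = 0; s < n; ++s) dx[s] = 0.0;
  for (int t = 0; t < nt; ++t)
    dx[s_sp[t] - 1] += s_co[t] * flux[s_rx[t] - 1];
}

// [[Rcpp::export]]
NumericVector rn_rhs_cpp(NumericVector x, NumericVector k,
                         IntegerVector r1, IntegerVector r2,
                         IntegerVector s_sp, IntegerVector s_rx,
                         NumericVector s_co, int nspecies) {
  int nr = k.size();
  std::vector<double> flux(nr);
  NumericVector dx(nspecies);
  masact_rhs(nspecies, nr, x.begin(), k.begin(), r1.begin(), r2.begin(),
             s_sp.size(), s_sp.begin(), s_rx.begin(), s_co.begin(),
             flux.data(), dx.begin());
  return dx;
}

// Analytic Jacobian of the mass-action RHS (dense, species x species,
// column-major in `J` with leading dimension ldj).

static void masact_jac(int n, int nr, const double *x, const double *k,
                       const int *r1, const int *r2,
                       int nt, const int *s_sp, const int *s_rx,
                       const double *s_co, double *J, int ldj) {
  std::vector<int> dcol1(nr, 0), dcol2(nr, 0);
  std::vector<double> dval1(nr, 0.0), dval2(nr, 0.0);
  for (int j = 0; j < nr; ++j) {
    int a = r1[j], b = r2[j];
    if (a > 0 && b > 0) {
      if (a == b) {
        dcol1[j] = a;
        dval1[j] = 2.0 * k[j] * x[a - 1];
      } else {
        dcol1[j] = a;
        dval1[j] = k[j] * x[b - 1];
        dcol2[j] = b;
        dval2[j] = k[j] * x[a - 1];
      }
    } else if (a > 0) {
      dcol1[j] = a;
      dval1[j] = k[j];
    }
  }
  for (int c = 0; c < n; ++c)
    for (int s = 0; s < n; ++s) J[c * ldj + s] = 0.0;
  for (int t = 0; t < nt; ++t) {
    int j = s_rx[t] - 1;
    int s = s_sp[t] - 1;
    if (dcol1[j] > 0) J[(dcol1[j] - 1) * ldj + s] += s_co[t] * dval1[j];
    if (dcol2[j] > 0) J[(dcol2[j] - 1) * ldj + s] += s_co[t] * dval2[j];
  }
}

// [[Rcpp::export]]
NumericMatrix rn_jac_cpp(NumericVector x, NumericVector k,
                         IntegerVector r1, IntegerVector r2,
                         IntegerVector s_sp, IntegerVector s_rx,
                         NumericVector s_co, int nspecies) {
  int nr = k.size();
  NumericMatrix J(nspecies, nspecies);
  masact_jac(nspecies, nr, x.begin(), k.begin(), r1.begin(), r2.begin(),
             s_sp.size(), s_sp.begin(), s_rx.begin(), s_co.begin(),
             J.begin(), nspecies);
  return J;
}

// ---- native deSolve interface --------------------------------------------
// The current system is staged into static storage with rn_set_system();
// deSolve then calls rn_derivs/rn_jacobian directly, avoiding an R callback
// per step.  An optional linear ramp on one rate parameter supports
// rate-constant drift sweeps: for reactions in ramp_idx, k(t) =
// ramp_base * (p0 + (p1 - p0) * clamp(t / T, 0, 1)).

static std::vector<double> g_k;
static std::vector<int> g_r1, g_r2, g_ssp, g_srx;
static std::vector<double> g_sco, g_flux;
static int g_n = 0, g_nr = 0, g_nt = 0;
static std::vector<int> g_ramp_idx;
static std::vector<double> g_ramp_base;
static double g_ramp_p0 = 0.0, g_ramp_p1 = 0.0, g_ramp_T = 1.0;
static bool g_ramp = false;

// [[Rcpp::export]]
void rn_set_system(NumericVector k, IntegerVector r1, IntegerVector r2,
                   IntegerVector s_sp, IntegerVector s_rx, NumericVector s_co,
                   int nspecies) {
  g_k.assign(k.begin(), k.end());
  g_r1.assign(r1.begin(), r1.end());
  g_r2.assign(r2.begin(), r2.end());
  g_ssp.assign(s_sp.begin(), s_sp.end());
  g_srx.assign(s_rx.begin(), s_rx.end());
  g_sco.assign(s_co.begin(), s_co.end());
  g_n = nspecies;
  g_nr = k.size();
  g_nt = s_sp.size();
  g_flux.assign(g_nr, 0.0);
  g_ramp = false;
}

// [[Rcpp::export]]
void rn_set_ramp(IntegerVector idx, NumericVector base, double p0, double p1,
                 double T) {
  g_ramp_idx.assign(idx.begin(), idx.end());
  g_ramp_base.assign(base.begin(), base.end());
  g_ramp_p0 = p0;
  g_ramp_p1 = p1;
  g_ramp_T = T;
  g_ramp = true;
}

static void apply_ramp(double t) {
  if (!g_ramp) return;
  double u = t / g_ramp_T;
  if (u < 0.0) u = 0.0;
  if (u > 1.0) u = 1.0;
  double p = g_ramp_p0 + (g_ramp_p1 - g_ramp_p0) * u;
  for (size_t i = 0; i < g_ramp_idx.size(); ++i)
    g_k[g_ramp_idx[i] - 1] = g_ramp_base[i] * p;
}

extern "C" {

void rn_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip);
void rn_jacobian(int *neq, double *t, double *y, int *ml, int *mu, double *pd,
                 int *nrowpd, double *yout, int *ip);

void rn_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip) {
  (void)neq; (void)yout; (void)ip;
  apply_ramp(*t);
  masact_rhs(g_n, g_nr, y, g_k.data(), g_r1.data(), g_r2.data(), g_nt,
             g_ssp.data(), g_srx.data(), g_sco.data(), g_flux.data(), ydot);
}

void rn_jacobian(int *neq, double *t, double *y, int *ml, int *mu, double *pd,
                 int *nrowpd, double *yout, int *ip) {
  (void)neq; (void)ml; (void)mu; (void)yout; (void)ip;
  apply_ramp(*t);
  masact_jac(g_n, g_nr, y, g_k.data(), g_r1.data(), g_r2.data(), g_nt,
             g_ssp.data(), g_srx.data(), g_sco.data(), pd, *nrowpd);
}

}
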