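/* Compiled right-hand side of the semi-PBPK system.
 *
 * Mirrors the reference R implementation (pbpk_rhs) exactly; the R engine
 * remains available and the test suite asserts agreement between the two.
 *
 * Parameter vector layout (doubles, fixed length MAXPAR, zero-padded):
 *   header (20):
 *     0 q_la  1 q_pv  2 q_k  3 q_l  4-6 q_gw  7 sum(q_gw)  8 v_pv
 *     9-12 k_t (stomach, duodenum, jejunum, ileum)  13-15 ka (segments)
 *     16 oral flag  17 metabolite mass factor  18 has-metabolite flag
 *     19 infusion rate (mg/min)
 *   parent species block, then (optionally) metabolite species block:
 *     0 v_sys  1 fu_b  2-4 rb/(K_GP*V_GW) per segment  5 rb/(K_LP*V_L)
 *     6 rb/(K_KP*V_K)  7 CL_bile  8 CLint_K  9 k12  10 k21  11 k13  12 k31
 *     13 per2 flag  14 per3 flag  15 n linear pathways  16 n saturable
 *     then: CLint[n_lin], produces[n_lin], Vmax[n_sat], Km[n_sat],
 *           produces[n_sat]   (whole-liver mass units)
 *
 * State walk per species (amounts, mg): [stomach, 3 lumen] (oral only),
 * 3 gut wall, portal vein, liver, kidney, systemic, [per2], [per3],
 * cumulative eliminations per pathway, biliary, renal, [fecal],
 * then the metabolite block and its cumulative formation.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define MAXPAR 160
#define MAXPATH 8

static double P[MAXPAR];

void ces1pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = MAXPAR;
    odeparms(&n, P);
}

static int species_block_len(const double *sp)
{
    int nlin = (int) sp[15], nsat = (int) sp[16];
    return 17 + 2 * nlin + 3 * nsat;
}

static int species_deriv(const double *hdr, const double *sp,
                         const double *y, double *dy, int k, int oral,
                         double infusion, double form_in,
                         double *produced_out)
{
    const double q_la = hdr[0], q_pv = hdr[1], q_k = hdr[2], q_l = hdr[3];
    const double *qgw = hdr + 4;
    const double sumqgw = hdr[7], v_pv = hdr[8];
    const double *kt = hdr + 9, *ka = hdr + 13;

    double abs_in[3] = {0.0, 0.0, 0.0};
    double fecal_out = 0.0;

    if (oral) {
        double a_st = y[k], a1 = y[k + 1], a2 = y[k + 2], a3 = y[k + 3];
        abs_in[0] = ka[0] * a1;
        abs_in[1] = ka[1] * a2;
        abs_in[2] = ka[2] * a3;
        dy[k] = -kt[0] * a_st;
        dy[k + 1] = kt[0] * a_st - kt[1] * a1 - abs_in[0];
        dy[k + 2] = kt[1] * a1 - kt[2] * a2 - abs_in[1];
        dy[k + 3] = kt[2] * a2 - kt[3] * a3 - abs_in[2];
        fecal_out = kt[3] * a3;
        k += 4;
    }

    const int i_gw = k, i_pv = k + 3, i_liv = k + 4, i_kid = k + 5,
              i_sys = k + 6;
    k += 7;

    const double vsys = sp[0], fu = sp[1];
    const double *fgw = sp + 2;
    const double fliv = sp[5], fkid = sp[6];
    const double clbile = sp[7], clintk = sp[8];
    const double k12 = sp[9], k21 = sp[10], k13 = sp[11], k31 = sp[12];
    const int per2 = sp[13] > 0.5, per3 = sp[14] > 0.5;
    const int nlin = (int) sp[15], nsat = (int) sp[16];
    const double *lin_clint = sp + 17;
    const double *lin_prod = lin_clint + nlin;
    const double *sat_vmax = lin_prod + nlin;
    const double *sat_km = sat_vmax + nsat;
    const double *sat_prod = sat_km + nsat;

    const double c_sys = y[i_sys] / vsys;

    double sum_qc = 0.0;
    for (int j = 0; j < 3; j++) {
        double cgw_out = y[i_gw + j] * fgw[j];
        dy[i_gw + j] = abs_in[j] + qgw[j] * (c_sys - cgw_out);
        sum_qc += qgw[j] * cgw_out;
    }

    const double c_pv = y[i_pv] / v_pv;
    dy[i_pv] = sum_qc + (q_pv - sumqgw) * c_sys - q_pv * c_pv;

    const double c_l_out = y[i_liv] * fliv;
    const double cu = fu * c_l_out;
    double elim[MAXPATH];
    double elim_sum = 0.0, produced = 0.0;
    int ne = 0;
    for (int j = 0; j < nlin; j++) {
        double e = lin_clint[j] * cu;
        elim[ne++] = e;
        elim_sum += e;
        if (lin_prod[j] > 0.5) produced += e;
    }
    for (int j = 0; j < nsat; j++) {
        double e = sat_vmax[j] * cu / (sat_km[j] + cu);
        elim[ne++] = e;
        elim_sum += e;
        if (sat_prod[j] > 0.5) produced += e;
    }
    const double elim_bile = clbile * cu;
    dy[i_liv] = q_la * c_sys + q_pv * c_pv - q_l * c_l_out
                - elim_sum - elim_bile + form_in;

    const double c_k_out = y[i_kid] * fkid;
    const double elim_ren = clintk * fu * c_k_out;
    dy[i_kid] = q_k * (c_sys - c_k_out) - elim_ren;

    double d_sys = q_l * c_l_out + q_k * c_k_out
                   - (q_la + q_pv + q_k) * c_sys + infusion;
    if (per2) {
        int i_p2 = k++;
        d_sys += -k12 * y[i_sys] + k21 * y[i_p2];
        dy[i_p2] = k12 * y[i_sys] - k21 * y[i_p2];
    }
    if (per3) {
        int i_p3 = k++;
        d_sys += -k13 * y[i_sys] + k31 * y[i_p3];
        dy[i_p3] = k13 * y[i_sys] - k31 * y[i_p3];
    }
    dy[i_sys] = d_sys;

    for (int j = 0; j < ne; j++) dy[k + j] = elim[j];
    k += ne;
    dy[k++] = elim_bile;
    dy[k++] = elim_ren;
    if (oral) dy[k++] = fecal_out;

    *produced_out = produced;
    return k;
}

void ces1pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *hdr = P;
    const int oral = hdr[16] > 0.5, has_met = hdr[18] > 0.5;
    const double mass_factor = hdr[17], infusion = hdr[19];
    const double *par = P + 20;

    for (int i = 0; i < *neq; i++) ydot[i] = 0.0;

    double produced = 0.0;
    int next = species_deriv(hdr, par, y, ydot, 0, oral, infusion, 0.0,
                             &produced);
    if (has_met) {
        const double *met = par + species_block_len(par);
        double form = produced * mass_factor, p2 = 0.0;
        next = species_deriv(hdr, met, y, ydot, next, 0, 0.0, form, &p2);
        ydot[next] = form; /* cumulative metabolite formation */
    }
}

static const R_CMethodDef CEntries[] = {
    {"ces1pbpk_derivs", (DL_FUNC) &ces1pbpk_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_ces1pbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
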