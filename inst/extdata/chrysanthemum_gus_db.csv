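strains,od,od_wavelength_nm,ccp_days,kanamycin,hygromycin,paromomycin,geneticin,vancomycin,cefotaxime,carbenicillin,ticarcillin,efficiency_pct,reference
LBA4404,1.5,550,8,-,-,-,-,400,250,-,-,4.3–13.4,jong_ref068
LBA4404,0.8,550,4,25,-,-,-,100–300,-,-,-,0–4.6,lemieux_ref062
LBA4404;A2002,0.1,660,2,25,-,-,-,-,-,-,500,0–0.8,ledger_ref059
LBA4404;A281;Ach5;C58,0.5,660,6,50,-,-,-,400,250,-,-,0–0.75,vanwordragen_ref069
EHA101,0.1,660,3,35,-,-,-,-,250,-,-,0.06,aida_ref070
LBA4404;A281;Ach5,0.5,660,2,50,-,-,-,400,250,-,-,0–10,vanwordragen_ref071
LBA4404,0.6,660,2,-,-,-,-,400,250,-,-,1.4–4.6,dejong_ref066
LBA4404,0.1,660,4,-,-,-,-,-,-,500,-,0–0.4,courtneygutterson_ref072
EHA101;Ach5;C58;Bo542,0.7,660,1,25,5,-,-,400,500,-,-,1.04–12.14,renou_ref042
LBA4404;C58,0.5,660,2,15–25,-,-,-,-,500,-,-,0–6.3,lowe_ref073
A281,0.5,660,3,50–100,-,-,-,200,125,-,-,0–2.5,vanwordragen_ref074
LBA4404,0.1,660,3–5,100,-,-,-,-,-,500,-,0–0.4,courtneygutterson_ref075
B6S3,0.1,660,1,100,-,-,-,-,200,-,500,17–47,pavingerova_ref039
LBA4404;AGL0,0.4–0.8,550,2,10–25,-,-,-,400,250,-,-,0.3–4.3,dejong_ref041
EHA105;Ach5;A281;Chry5,2.2,660,3–5,50,-,-,-,-,-,500,-,4–7,urban_ref043
B6S3,0.1,660,1,100,-,-,-,-,200,-,500,3.8–4.7,benetka_ref040
AGL0,0.5,540,2,10,-,-,-,500,250,-,-,0–39.45,dejong_ref076
C58;A281,0.1,660,2,25,-,-,-,-,500,-,-,0–11.3,dolgov_ref077
AGL0,0.7–1,540,2,10,-,-,-,400,250,-,-,5.6–15.6,fukai_ref064
LBA4404,0.5,540,2,50,-,-,-,-,100,-,-,6.9–8.3,oka_ref078
A281;GV3101;C58;CBE21,0.6–0.9,600,3,10–50,10–15,-,-,-,500,-,-,0–3,dolgov_ref079
LBA4404,0.1,660,4,20,-,-,-,-,-,-,500,3.4,boase_ref080
LBA4404;EHA105+2xMOG,0.1,660,4,25,-,-,-,-,-,-,500,0–14.2,boase_ref081
LBA4404,0.5,600,4,25,-,-,-,-,500,-,-,3.4–8.5,fu_ref082
LBA4404,0.5,600,2,20,-,-,-,-,250,-,-,6.9,kim_ref083
LBA4404,0.5,600,2,50,-,-,-,-,250,-,-,7.6,kim_ref084
EHA105,2.2,600,5,-,-,50,-,-,-,500,-,0.5–4.1,john_ref085
EHA101,0.2,600,3,15,15,-,15,-,250,-,-,3.4,shinoyama_ref086
LBA4404,0.5,660,3,15,15,-,15,-,250,-,-,0–2.5,takatsu_ref087
LBA4404,0.1,660,3,20,-,-,-,-,250,-,-,1.3–3.1,young_ref088
LBA4404,0.5,600,2,25,-,-,-,-,250,-,-,6.4%,shao_ref089
C58;MP90,0.5,600,2,50,-,-,-,-,250,-,-,1.12–1.91,takatsu_ref044
EHA101,0.2,600,3,-,-,-,20–30,-,250,-,-,3.4,shinoyama_ref060
EHA101,0.5,600,3,-,10–40,-,-,-,-,500,-,0–2.5,shirasawa_ref090
EHA101,1.8,660,2,100,-,-,-,125,500,-,-,0–2.3,tosca_ref091
AGL0,0.7–1,540,2,25,-,-,-,-,125,-,100,0–6.8,annadana_ref065
EHA105,2,600,2,50,-,-,-,-,-,500,-,3.4–11.4,zhiliang_ref092
LBA4404;AGL0,0.2,600,3,12.5,-,-,-,-,250,-,-,0.5–4.7,ishida_ref093
LBA4404,0.5,600,3,50,-,-,-,-,500,-,-,1.2–9.4,jeong_ref094
EHA101;LBA4404;AGL0,0.1,600,4,50,-,-,-,-,-,-,200,3.4–5.9,kudo_ref095
LBA4404,0.1,600,2,-,-,-,20,-,250,-,-,0–23.9,shinoyama_ref061
LBA4404;AGL0,0.6,550,3–4,30,-,-,-,-,500,-,-,0–25,teixeiradasilva_ref067
LBA4404;AGL0,0.1,600,-,12.5,-,-,-,-,250,-,-,27–38,toguri_ref096
AGL0,0.7–1,540,4,10,-,-,-,400,250,-,-,31–39,petty_ref097
AGL0,0.8,550,6,25,-,-,-,500,250,-,-,4.7–13.4,outchkourov_ref098
EHA105;AGL0,0.1,660,8,-,-,50,-,-,250,-,-,0.5–6.5,aida_ref063
EHA105,0.1,660,5,-,-,50,-,-,250,-,-,0.5–6.8,aida_ref099
EHA105,0.1,660,4,-,-,50,-,-,250,-,-,0–0.6,aida_ref100
EHA105,0.1,660,3,50,-,-,20,-,250,-,-,37,shinoyama_ref009
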