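case_id,marker,result,original_diagnosis,site
MCL-atypical,CD20,+,Mantle cell lymphoma,nodal
MCL-atypical,Bcl-2,+,Mantle cell lymphoma,nodal
MCL-atypical,CD3,-,Mantle cell lymphoma,nodal
MCL-atypical,CD10,-,Mantle cell lymphoma,nodal
MCL-atypical,Bcl-6,-,Mantle cell lymphoma,nodal
MCL-atypical,CD23,-,Mantle cell lymphoma,nodal
MCL-atypical,MUM1,-,Mantle cell lymphoma,nodal
MCL-atypical,p53,-,Mantle cell lymphoma,nodal
FL-classic,CD20,+,Follicular lymphoma,nodal
FL-classic,CD10,+,Follicular lymphoma,nodal
FL-classic,Bcl-2,+,Follicular lymphoma,nodal
FL-classic,Bcl-6,+,Follicular lymphoma,nodal
FL-classic,CD5,-,Follicular lymphoma,nodal
FL-classic,Cyclin D1,-,Follicular lymphoma,nodal
CHL-classic,CD30,+,"Classical Hodgkin lymphoma, NOS",nodal
CHL-classic,CD15,+,"Classical Hodgkin lymphoma, NOS",nodal
CHL-classic,PAX5,+,"Classical Hodgkin lymphoma, NOS",nodal
CHL-classic,CD3,-,"Classical Hodgkin lymphoma, NOS",nodal
CHL-classic,CD20,-,"Classical Hodgkin lymphoma, NOS",nodal
ENKTL-nasal,CD3,+,ENKTL,extranodal
ENKTL-nasal,CD56,+,ENKTL,extranodal
ENKTL-nasal,EBER,+,ENKTL,extranodal
ENKTL-nasal,CD20,-,ENKTL,extranodal
ENKTL-nasal,CD5,-,ENKTL,extranodal
sparse-panel,CD20,+,Follicular lymphoma,NA
sparse-panel,CD3,-,Follicular lymphoma,NA
prognostic-only,p53,+,"Diffuse large B-cell lymphoma, NOS",NA
prognostic-only,EGFR,-,"Diffuse large B-cell lymphoma, NOS",NA
prognostic-only,Ki-67,+,"Diffuse large B-cell lymphoma, NOS",NA
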